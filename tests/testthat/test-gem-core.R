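test_that("model constructor enforces its invariants", {
  mets <- data.frame(id = c("a_c", "b_c"))
  good <- data.frame(id = "R1", lb = 0, ub = 10, gpr = "", pathway = "P")
  good$stoich <- list(c(a_c = -1, b_c = 1))
  expect_s3_class(metabolic_model(mets, good), "metabolic_model")

  bad_met <- good; bad_met$stoich <- list(c(a_c = -1, zz_c = 1))
  expect_error(metabolic_model(mets, bad_met), "unknown metabolite")
  bad_bounds <- good; bad_bounds$lb <- 20
  expect_error(metabolic_model(mets, bad_bounds), "lower bound exceeds")
  bad_coef <- good; bad_coef$stoich <- list(c(a_c = 0, b_c = 1))
  expect_error(metabolic_model(mets, bad_coef), "zero coefficients")
  expect_error(
    metabolic_model(data.frame(id = c("a", "b_c")), good),
    "compartment tag")
})

test_that("GPR parsing reproduces boolean structure and rejects bad input", {
  expect_equal(parse_gpr("G1 and G2"),
               list(op = "and", args = list(list(op = "gene", gene = "G1"),
                                            list(op = "gene", gene = "G2"))))
  tree <- parse_gpr("(G1 and G2) or G3")
  expect_equal(tree$op, "or")
  expect_equal(tree$args[[1]]$op, "and")
  expect_equal(tree$args[[2]]$gene, "G3")
  expect_null(parse_gpr(""))
  expect_null(parse_gpr(NA))

  expect_error(parse_gpr("(G1 and G2"), "unbalanced|unexpected")
  expect_error(parse_gpr("G1 and or G2"), "unexpected")
  expect_error(parse_gpr("G1 G2"), "unexpected")

  # deparse is a parse inverse (round-trip on nested rules)
  for (rule in c("G1", "G1 and G2", "(G1 or G2) and (G3 or (G4 and G5))")) {
    expect_equal(parse_gpr(deparse_gpr(parse_gpr(rule))), parse_gpr(rule))
  }
})

test_that("reaction classification partitions reactions by structural rules", {
  mets <- data.frame(id = c("glc_e", "glc_c", "pyr_c", "pyr_m", "x_c"))
  rxns <- data.frame(
    id = c("EX_glc", "T_glc", "GLY1", "T_pyr", "DM_x", "MIX"),
    lb = c(-10, 0, 0, -10, 0, 0), ub = 10,
    gpr = "", pathway = c("", "Transport", "Glycolysis", "Transport", "", "Mixed"))
  rxns$stoich <- list(
    c(glc_e = -1),                      # boundary, extracellular -> exchange
    c(glc_e = -1, glc_c = 1),           # transport
    c(glc_c = -1, pyr_c = 1),           # metabolic
    c(pyr_c = -1, pyr_m = 1),           # transport (same base id, two compartments)
    c(x_c = -1),                        # intracellular sink -> demand
    c(glc_c = -1, pyr_c = 1, pyr_m = 1) # transport + transformation -> metabolic
  )
  m <- metabolic_model(mets, rxns)
  cls <- classify_reactions(m)
  expect_equal(unname(cls[c("EX_glc", "T_glc", "GLY1", "T_pyr", "DM_x")]),
               c("exchange", "transport", "metabolic", "transport", "demand"))
  expect_equal(unname(cls[["MIX"]]), "metabolic")
  # total function: every reaction gets exactly one class
  expect_setequal(names(cls), m$reactions$id)
  expect_true(all(cls %in% c("metabolic", "exchange", "demand", "transport",
                             "unassigned")))
  # unassigned label dominates for non-boundary, non-transport reactions
  rxns2 <- rxns; rxns2$pathway[3] <- ""
  m2 <- metabolic_model(mets, rxns2)
  expect_equal(unname(classify_reaction(m2, "GLY1")), "unassigned")
})

test_that("pathway classification honors the essential-amino-acid exception", {
  mets <- data.frame(id = c("his_L_e", "his_L_c", "foo_e", "foo_c"))
  rxns <- data.frame(
    id = c("T_his", "T_foo"), lb = 0, ub = 10, gpr = "",
    pathway = c("His transport", "Foo transport"))
  rxns$stoich <- list(c(his_L_e = -1, his_L_c = 1), c(foo_e = -1, foo_c = 1))
  m <- metabolic_model(mets, rxns)
  expect_equal(classify_pathway(m, "His transport"), "transport_essential_aa")
  expect_equal(classify_pathway(m, "Foo transport"), "transport")
  expect_setequal(eligible_pathways(m), "His transport")
})

test_that("currency lookup is compartment-invariant and overridable", {
  expect_true(all(is_currency(c("atp_c", "atp_m", "h2o_e", "NADPH_c"))))
  expect_false(any(is_currency(c("akg_c", "glc_e"))))
  custom <- withr::local_tempfile(lines = c("# custom", "akg"))
  expect_true(is_currency("akg_m", currency = read_id_list(custom)))
  expect_error(read_id_list(withr::local_tempfile(lines = "# only comments")),
               "empty")
})

test_that("SBML write/read round-trip preserves the model exactly", {
  model <- generate_toy_gem(toy_gem_spec(n_pathways = 3, n_shared = 1, seed = 11))
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(model, path)
  m2 <- read_sbml(path)
  expect_identical(m2$metabolites$id, model$metabolites$id)
  expect_identical(m2$reactions$id, model$reactions$id)
  expect_identical(m2$reactions$pathway, model$reactions$pathway)
  expect_identical(m2$reactions$stoich, model$reactions$stoich)
  expect_equal(m2$reactions$lb, model$reactions$lb)
  expect_equal(m2$reactions$ub, model$reactions$ub)
  expect_identical(lapply(m2$reactions$gpr, parse_gpr),
                   lapply(model$reactions$gpr, parse_gpr))
  # write is deterministic byte-for-byte
  path2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(model, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("read_sbml error contracts", {
  expect_error(read_sbml(tempfile()), "not found")
  junk <- withr::local_tempfile(lines = "<not-sbml>")
  expect_error(read_sbml(junk), "parse error")
  # SBML without fbc bounds is rejected, naming the reaction
  no_bounds <- withr::local_tempfile(lines = c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfSpecies>',
    '<species id="M_a_c" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="R_r1" reversible="false">',
    '<listOfReactants><speciesReference species="M_a_c" stoichiometry="1"/>',
    '</listOfReactants></reaction></listOfReactions></model></sbml>'))
  expect_error(read_sbml(no_bounds), "R_r1.*bounds")
})

test_that("read_sbml agrees with libsbml/cobra on a toy fixture", {
  # independent oracle: python-libsbml via cobra reads the same file
  python <- Sys.which("python")
  model <- generate_toy_gem(toy_gem_spec(n_pathways = 3, n_shared = 1, seed = 5))
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(model, path)
  out <- withr::local_tempfile(fileext = ".json")
  script <- sprintf('
import json, cobra
m = cobra.io.read_sbml_model("%s")
json.dump({
  "reactions": sorted(r.id for r in m.reactions),
  "metabolites": sorted(x.id for x in m.metabolites),
  "bounds": {r.id: [r.lower_bound, r.upper_bound] for r in m.reactions},
  "gpr": {r.id: str(r.gpr) for r in m.reactions},
}, open("%s", "w"))', path, out)
  sf <- withr::local_tempfile(lines = script, fileext = ".py")
  expect_equal(system2(python, sf, stdout = FALSE, stderr = FALSE), 0L)
  ref <- jsonlite::fromJSON(out)
  expect_equal(ref$reactions, sort(model$reactions$id))
  expect_equal(ref$metabolites, sort(model$metabolites$id))
  for (r in model$reactions$id) {
    expect_equal(unlist(ref$bounds[[r]]),
                 c(model$reactions$lb[model$reactions$id == r],
                   model$reactions$ub[model$reactions$id == r]))
    expect_equal(parse_gpr(ref$gpr[[r]]),
                 parse_gpr(model$reactions$gpr[model$reactions$id == r]))
  }
})
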