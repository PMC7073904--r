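test_that("auxotroph recipe contains the documented edits", {
  recipe <- base_curation_recipe()
  actions <- vapply(recipe, `[[`, character(1), "action")
  targets <- vapply(recipe, `[[`, character(1), "target")
  expect_identical(sort(targets[actions == "remove_reaction"]),
                   sort(c("POR5", "GLYCK", "PFL", "OBTFL", "FTHFLi")))
  expect_identical(sort(targets[actions == "knockout"]),
                   sort(c("GLYCL", "GHMT2r")))
  expect_identical(sort(targets[actions == "make_irreversible"]),
                   sort(c("FTHFD", "GARFT", "AICART")))
  expect_identical(targets[actions == "make_reversible"], "THYMt3pp")
  thfspont <- recipe[[which(targets == "THFSPONT")]]$payload
  expect_equal(thfspont$stoichiometry[c("thf_c", "fald_c", "mlthf_c", "h2o_c")],
               c(thf_c = -1, fald_c = -1, mlthf_c = 1, h2o_c = 1))
  expect_gte(thfspont$lower_bound, 0)  # net condensation is irreversible
})

test_that("serine-cycle recipe carries the quoted stoichiometries", {
  recipe <- serine_cycle_recipe()
  actions <- vapply(recipe, `[[`, character(1), "action")
  targets <- vapply(recipe, `[[`, character(1), "target")
  expect_identical(sort(targets[actions == "remove_reaction"]),
                   sort(c("GLXCL", "GLYCL", "THRD", "THRA2", "THRA",
                          "SERD_L")))
  pay <- function(id) recipe[[which(targets == id)]]$payload$stoichiometry
  expect_equal(pay("MCL"), c(malylcoa_c = -1, accoa_c = 1, glx_c = 1))
  expect_equal(pay("MTK")[c("mal__L_c", "atp_c", "coa_c", "malylcoa_c",
                            "adp_c", "pi_c")],
               c(mal__L_c = -1, atp_c = -1, coa_c = -1, malylcoa_c = 1,
                 adp_c = 1, pi_c = 1))
  expect_equal(pay("SGAT1")[c("ser__L_c", "akg_c", "glu__L_c", "hpyr_c")],
               c(ser__L_c = -1, akg_c = -1, glu__L_c = 1, hpyr_c = 1))
  expect_equal(pay("SGAT2")[c("gly_c", "akg_c", "glx_c", "glu__L_c")],
               c(gly_c = -1, akg_c = -1, glx_c = 1, glu__L_c = 1))
  expect_equal(pay("EtMaCoA")[c("b2coa_c", "nadph_c", "co2_c", "q8_c",
                                "h2o_c", "glx_c", "ppcoa_c", "nadp_c",
                                "q8h2_c")],
               c(b2coa_c = -1, nadph_c = -1, co2_c = -1, q8_c = -1,
                 h2o_c = -1, glx_c = 1, ppcoa_c = 1, nadp_c = 1, q8h2_c = 1))
  expect_equal(pay("MMCDr")[c("ppcoa_c", "atp_c", "hco3_c", "mmcoa__S_c",
                              "adp_c", "h_c", "pi_c")],
               c(ppcoa_c = -1, atp_c = -1, hco3_c = -1, mmcoa__S_c = 1,
                 adp_c = 1, h_c = 1, pi_c = 1))
  expect_true("MMM" %in% targets[actions == "make_reversible"])
})

test_that("applying the auxotroph recipe edits only its targets", {
  raw <- gen_toy_model(0.7, "auxotroph", curated = FALSE)
  cur <- apply_curation(raw, base_curation_recipe())
  expect_identical(length(cur$reactions), length(raw$reactions) - 5L + 1L)
  recipe_targets <- vapply(base_curation_recipe(), `[[`, character(1),
                           "target")
  untouched <- setdiff(names(raw$reactions), recipe_targets)
  for (id in untouched) {
    expect_identical(cur$reactions[[id]], raw$reactions[[id]])
  }
  # knocked-out reactions are retained with zero bounds
  expect_equal(cur$reactions[["GHMT2r"]]$upper_bound, 0)
  expect_equal(cur$reactions[["GLYCL"]]$lower_bound, 0)
  # the transhydrogenase now translocates a single proton
  expect_equal(cur$reactions[["THD2pp"]]$stoichiometry[["h_p"]], -1)
  # the original model is untouched
  expect_false("THFSPONT" %in% names(raw$reactions))
})

test_that("recipe application is order-insensitive", {
  raw <- gen_toy_model(0.7, "auxotroph", curated = FALSE)
  ref <- canonical_model(apply_curation(raw, base_curation_recipe()))
  sraw <- gen_toy_model(20.8, "serine", curated = FALSE)
  sref <- canonical_model(
    apply_curation(apply_curation(sraw, base_curation_recipe()),
                   serine_cycle_recipe()))
  set.seed(11)
  for (rep in 1:3) {
    expect_identical(
      canonical_model(apply_curation(raw, sample(base_curation_recipe()))),
      ref)
    expect_identical(
      canonical_model(
        apply_curation(apply_curation(sraw, sample(base_curation_recipe())),
                       sample(serine_cycle_recipe()))),
      sref)
  }
})

test_that("second application of a recipe is a no-op or a clean error per edit", {
  raw <- gen_toy_model(0.7, "auxotroph", curated = FALSE)
  cur <- apply_curation(raw, base_curation_recipe())
  for (edit in base_curation_recipe()) {
    res <- try(apply_curation(cur, list(edit)), silent = TRUE)
    if (edit$action %in% c("remove_reaction", "add_reaction")) {
      expect_s3_class(res, "try-error")
      expect_match(attr(res, "condition")$message, "curation error")
      expect_match(attr(res, "condition")$message, edit$target, fixed = TRUE)
    } else {
      expect_identical(canonical_model(res), canonical_model(cur))
    }
  }
})

test_that("curation failures name the edit and target", {
  raw <- gen_toy_model(0.7, "auxotroph", curated = FALSE)
  expect_error(apply_curation(raw, list(
    curation_edit("remove_reaction", "FOO"))), "FOO")
  expect_error(apply_curation(raw, list(
    curation_edit("add_reaction", "GLYCL",
                  reaction("GLYCL", c(gly_c = -1))))),
    "already in model")
  expect_error(curation_edit("teleport", "GLYCL"), "arg")
})

test_that("the edit log records every step and serializes as TSV", {
  raw <- gen_toy_model(0.7, "auxotroph", curated = FALSE)
  cur <- apply_curation(raw, base_curation_recipe())
  log <- attr(cur, "edit_log")
  expect_identical(nrow(log), length(base_curation_recipe()))
  expect_identical(log$step, seq_len(nrow(log)))
  expect_true(all(c("action", "target", "before", "after") %in% names(log)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edit_log(cur, path)
  back <- utils::read.delim(path)
  expect_identical(nrow(back), nrow(log))
})

test_that("recipes survive a JSON round trip", {
  for (recipe in list(base_curation_recipe(), serine_cycle_recipe())) {
    path <- withr::local_tempfile(fileext = ".json")
    write_recipe_json(recipe, path)
    back <- read_recipe_json(path)
    raw <- gen_toy_model(20.8, "serine", curated = FALSE)
    if (identical(recipe[[1]]$target, "GLXCL")) {
      raw <- apply_curation(raw, base_curation_recipe())
    }
    expect_identical(canonical_model(apply_curation(raw, back)),
                     canonical_model(apply_curation(raw, recipe)))
  }
})
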