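# direct construction of a classified regimen row, bypassing assembly
reg_row <- function(sub, atc, category = NULL, n = 1) {
  out <- tibble::tibble(
    admission_id = sprintf("A%04d", seq_len(n)),
    sub_indication = sub,
    atc_key = paste(sort(atc), collapse = ";"))
  if (!is.null(category)) out$category <- category
  out
}

test_that("regimens classify as A, B, C or NOT_ASSESSED against the fixture", {
  gl <- synthetic_guideline()
  # cephalosporins for cystitis are discordant
  expect_equal(classify_regimen("J01DC02", "cystitis", gl), "C")
  expect_equal(classify_regimen("J01DD04", "cystitis", gl), "C")
  # ceftriaxone is recommended for complicated UTI
  expect_equal(classify_regimen("J01DD04", "complicated-UTI", gl), "A")
  expect_equal(classify_regimen("J01MA02", "complicated-UTI", gl), "B")
  # combination first choice for severe CAP
  expect_equal(classify_regimen(c("J01MA02", "J01DD04"), "CAP-s", gl), "A")
  # catch-all sub-indications are never scored
  expect_equal(classify_regimen("J01CA04", "other-RTI", gl), "NOT_ASSESSED")
  # first choice takes precedence over second
  expect_equal(classify_regimen("J01CA04", "CAP", gl), "A")
  expect_error(classify_regimen("J01CA04", "no-such-code", gl),
               "no-such-code")
})

test_that("matching is set-based: permutation and duplication never change the category", {
  gl <- synthetic_guideline()
  expect_equal(classify_regimen(c("J01DD04", "J01MA02"), "CAP-s", gl),
               classify_regimen(c("J01MA02", "J01DD04"), "CAP-s", gl))
  expect_equal(classify_regimen(c("J01DD04", "J01DD04"), "complicated-UTI", gl),
               "A")
  withr::local_seed(31)
  agents_pool <- c("J01CA04", "J01DD04", "J01MA02", "J01DC02")
  for (i in 1:25) {
    agents <- sample(agents_pool, sample(1:3, 1), replace = TRUE)
    sub <- sample(names(gl), 1)
    expect_equal(classify_regimen(agents, sub, gl),
                 classify_regimen(rev(agents), sub, gl))
  }
})

test_that("extra agents on top of a recommendation are discordant unless allowed", {
  gl <- synthetic_guideline()
  expect_equal(classify_regimen(c("J01CA04", "J01MA02"), "CAP", gl), "C")
  expect_equal(classify_regimen(c("J01CA04", "J01MA02"), "CAP", gl,
                                allow_extra_agents = TRUE), "A")
})

test_that("route constraints only bind under strict matching", {
  gl <- synthetic_guideline()
  expect_equal(classify_regimen("J01XE01", "cystitis", gl,
                                routes = "iv", route_strict = FALSE), "A")
  expect_equal(classify_regimen("J01XE01", "cystitis", gl,
                                routes = "iv", route_strict = TRUE), "C")
  expect_equal(classify_regimen("J01XE01", "cystitis", gl,
                                routes = "oral", route_strict = TRUE), "A")
})

test_that("classification agrees with an exhaustive oracle on random tables", {
  oracle <- function(agents, sub, gl) {
    e <- gl[[sub]]
    if (!e$assessable) return("NOT_ASSESSED")
    s <- sort(unique(agents))
    hits <- function(choice) {
      found <- FALSE
      for (r in choice) if (identical(sort(unique(r)), s)) found <- TRUE
      found
    }
    if (hits(e$first_choice)) "A" else if (hits(e$second_choice)) "B" else "C"
  }
  pool <- c("J01CA04", "J01DD04", "J01MA02", "J01DC02", "J01XE01")
  tax <- default_indication_taxonomy()
  withr::local_seed(123)
  for (i in 1:40) {
    codes <- sample(tax$code, sample(2:5, 1))
    spec_list <- lapply(codes, function(code) {
      regs <- unique(replicate(4, sort(sample(pool, sample(1:2, 1))),
                               simplify = FALSE))
      keys <- vapply(regs, paste, character(1), collapse = ";")
      regs <- regs[!duplicated(keys)]
      k <- length(regs)
      n1 <- sample(seq_len(k), 1)
      list(assessable = TRUE,
           first_choice = regs[seq_len(n1)],
           second_choice = if (n1 < k) regs[(n1 + 1):k] else list())
    })
    names(spec_list) <- codes
    gl <- as_guideline_table(spec_list)
    for (j in 1:5) {
      agents <- sample(pool, sample(1:3, 1), replace = TRUE)
      sub <- sample(codes, 1)
      expect_equal(classify_regimen(agents, sub, gl),
                   oracle(agents, sub, gl))
    }
  }
})

test_that("every assessable regimen receives exactly one category", {
  co <- generate_cohort(sim_config(n_patients = 200, seed = 3))
  sel <- run_selection(co$prescriptions, co$admissions)
  cls <- classify_regimens(assemble_regimens(sel$records), co$guideline)
  expect_true(all(cls$category %in% c("A", "B", "C", "NOT_ASSESSED")))
  gl <- co$guideline
  assessable <- vapply(cls$sub_indication,
                       function(s) gl[[s]]$assessable, logical(1))
  expect_true(all((cls$category == "NOT_ASSESSED") == !assessable))
})

test_that("adherence summary arithmetic and pooling behave as specified", {
  reg <- dplyr::bind_rows(
    reg_row("complicated-UTI", "J01DD04", "A", 6),
    reg_row("complicated-UTI", "J01MA02", "B", 2),
    reg_row("complicated-UTI", "J01DC02", "C", 2))
  rep <- adherence_summary(reg)
  b <- rep$by_subindication
  expect_equal(c(b$prop_A, b$prop_B, b$prop_C), c(0.6, 0.2, 0.2))
  expect_equal(b$adherence_rate, 0.8)
  expect_equal(b$prop_A + b$prop_B + b$prop_C, 1, tolerance = 1e-12)
  repA <- adherence_summary(reg, adherence_tier = "A")
  expect_equal(repA$by_subindication$adherence_rate, 0.6)

  # a combination at 3% of 100 regimens pools into "other"
  reg2 <- dplyr::bind_rows(
    reg_row("cystitis", "J01XE01", "A", 97),
    reg_row("cystitis", "J01DC02", "C", 3))
  rep2 <- adherence_summary(reg2, display_threshold = 0.05)
  pooled <- rep2$combinations
  expect_true("other" %in% pooled$combination)
  expect_equal(pooled$n[pooled$combination == "other"], 3)
  detail <- rep2$combinations_detail
  expect_equal(sum(detail$share[detail$share < 0.05]),
               pooled$share[pooled$combination == "other"])
  expect_equal(sum(pooled$share), 1, tolerance = 1e-12)
})

test_that("a seeded synthetic cohort recovers the planted adherent fraction", {
  cfg <- sim_config(n_patients = 450, seed = 17,
                    tract_mix = c(RTI = 0.6, UTI = 0.4, other = 0),
                    class_mix = c(empiric = 1, targeted = 0, prophylaxis = 0),
                    underage_fraction = 0, icu_fraction = 0,
                    short_stay_fraction = 0, readmission_fraction = 0,
                    dual_tract_fraction = 0, erroneous_start_fraction = 0,
                    misselection_rate = 0)
  co <- generate_cohort(cfg)
  sel <- run_selection(co$prescriptions, co$admissions)
  cls <- classify_regimens(assemble_regimens(sel$records), co$guideline)
  rep <- adherence_summary(cls)
  n <- rep$overall$n
  expect_gt(n, 300)
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(rep$overall$adherence_rate, ci[1])
  expect_lte(rep$overall$adherence_rate, ci[2])
})

test_that("the benchmark table brackets planted adherence and tolerates taxonomy gaps", {
  mk <- function(nA, nC) {
    adherence_summary(dplyr::bind_rows(
      reg_row("complicated-UTI", "J01DD04", "A", nA),
      reg_row("complicated-UTI", "J01DC02", "C", nC)))
  }
  bench <- benchmark_table(list(X = mk(30, 70), Y = mk(60, 40)))
  rng <- bench$adherence_range
  expect_equal(rng$min_adherence_pct, 30)
  expect_equal(rng$max_adherence_pct, 60)

  one <- benchmark_table(list(X = mk(30, 70)))
  expect_equal(one$adherence_range$min_adherence_pct,
               one$adherence_range$max_adherence_pct)

  # hospital without the CAP severity split contributes a CAP row only
  unsplit <- adherence_summary(reg_row("CAP", "J01CA04", "A", 10))
  split <- adherence_summary(dplyr::bind_rows(
    reg_row("CAP-m", "J01CA04", "A", 5),
    reg_row("CAP-s", "J01DD04;J01MA02", "A", 5)))
  bench2 <- benchmark_table(list(H1 = unsplit, H2 = split))
  h1 <- bench2$by_hospital[bench2$by_hospital$hospital == "H1", ]
  expect_equal(h1$sub_indication, "CAP")

  odd <- adherence_summary(reg_row("CAP-x", "J01CA04", "A", 5))
  expect_warning(benchmark_table(list(H1 = odd)), "CAP-x")
})
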