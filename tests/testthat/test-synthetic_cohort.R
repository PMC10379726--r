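test_that("cohort generation is deterministic and follows the visit schedule", {
  co1 <- small_cohort(n_infants = 10L, seed = 3L)
  co2 <- small_cohort(n_infants = 10L, seed = 3L)
  expect_identical(co1, co2)
  co3 <- small_cohort(n_infants = 10L, seed = 4L)
  expect_false(identical(co1$counts, co3$counts))

  expect_true(all(co1$metadata$visit %in% c("V0", "V1", "V3", "V6")))
  # V1/V3 are offsets from enrollment; V6 is at 365 days of age
  m <- co1$metadata
  v0 <- m[m$visit == "V0", c("infant_id", "age")]
  for (v in c("V1", "V3")) {
    off <- c(V1 = 30, V3 = 90)[[v]]
    sub <- m[m$visit == v, ]
    expect_equal(sub$age,
                 v0$age[match(sub$infant_id, v0$infant_id)] + off)
  }
  expect_true(all(m$age[m$visit == "V6"] == 365))
})

test_that("zero dropout yields exactly 4 visits per infant", {
  co <- generate_cohort(cohort_config(n_infants = 10L, dropout_prob = 0),
                        seed = 2L)
  expect_equal(nrow(co$metadata), 40L)
  expect_equal(as.vector(table(co$metadata$infant_id)), rep(4L, 10L))
  # every sample appears in every table exactly once
  expect_setequal(rownames(co$counts), co$metadata$sample_id)
  expect_setequal(rownames(co$metabolites), co$metadata$sample_id)
  expect_setequal(rownames(co$ko), co$metadata$sample_id)
  expect_true(all(co$truth_fct %in% seq_len(co$truth_params$n_fct)))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(arm_ratio = 1.2), "arm_ratio")
  expect_error(cohort_config(treatment_hazard_ratio = 0), "treatment_hazard_ratio")
  expect_error(cohort_config(n_fct = 1), "alpha_matrix|n_fct")
  cfg <- cohort_config()
  cfg$alpha_matrix[1, 1] <- -1
  expect_error(validate_cohort_config(cfg), "alpha_matrix")
})

test_that("trajectories are monotone and obey rate limits", {
  cfg0 <- cohort_config(base_hazards = rep(0, 4))
  tr <- simulate_fct_trajectory(30, "control", cfg0, seed = 1L)
  expect_equal(tr$fct, 1L)

  cfg_inf <- cohort_config(base_hazards = rep(1e6, 4))
  tr <- simulate_fct_trajectory(30, "control", cfg_inf, seed = 1L)
  expect_equal(max(tr$fct), 5L)
  expect_lt(max(tr$age), 1)

  cfg <- cohort_config()
  for (s in 1:20) {
    tr <- simulate_fct_trajectory(50, "test", cfg, seed = s)
    expect_true(all(diff(tr$fct) > 0))
    expect_true(all(diff(tr$age) > 0))
  }
})

test_that("a protective hazard ratio delays reaching late community types", {
  cfg <- cohort_config(treatment_hazard_ratio = 0.5)
  age_fct3 <- function(arm, seeds) {
    vapply(seeds, function(s) {
      tr <- simulate_fct_trajectory(30, arm, cfg, seed = s)
      tr$age[match(3L, tr$fct)]
    }, 1)
  }
  ctrl <- age_fct3("control", 1:2000)
  test <- age_fct3("test", 2001:4000)
  expect_gt(mean(test), mean(ctrl))
})

test_that("genus counts are Dirichlet-multinomial draws with the right moments", {
  cfg <- cohort_config()
  cnt <- draw_genus_counts(2L, 5000L, cfg, seed = 9L)
  expect_equal(sum(cnt), 5000L)
  expect_true(all(cnt >= 0))
  expect_error(draw_genus_counts(9L, 100L, cfg), "unknown fct_label")

  # concentrated alpha puts nearly all reads on the first taxon
  cfg2 <- cohort_config(n_fct = 2L,
                        alpha_matrix = rbind(c(1000, rep(0.01, 4)),
                                             rep(1, 5)),
                        base_hazards = 1 / 100)
  cnt2 <- draw_genus_counts(1L, 10000L, cfg2, seed = 1L)
  expect_gt(cnt2[1] / sum(cnt2), 0.99)

  # E[p] = alpha / sum(alpha)
  cfg3 <- cohort_config(n_fct = 2L,
                        alpha_matrix = rbind(c(2, 1, 1), c(1, 1, 1)),
                        base_hazards = 1 / 100)
  props <- t(vapply(1:10000, function(s) {
    draw_genus_counts(1L, 200L, cfg3, seed = s) / 200
  }, numeric(3)))
  expect_equal(colMeans(props), c(0.5, 0.25, 0.25), tolerance = 0.02)
})

test_that("metabolome draws encode the treatment and baseline structure", {
  cfg <- cohort_config()
  # the control-arm 2'-FL baseline location is 86 nmol/g
  expect_equal(cfg$metabolite_spec$base[cfg$metabolite_spec$metabolite == "2'-FL"],
               86)
  draws <- function(arm, visit, seeds) {
    vapply(seeds, function(s) {
      draw_metabolome(2L, arm, cfg, visit = visit, seed = s)[["2'-FL"]]
    }, 1)
  }
  expect_gt(mean(draws("test", "V3", 1:1000)),
            mean(draws("control", "V3", 1001:2000)))
  # all 43 bile-acid analytes present and positive
  m <- draw_metabolome(1L, "control", cfg, seed = 1L)
  expect_true(all(bile_acid_panel() %in% names(m)))
  expect_true(all(m > 0))
})

test_that("a feature with identical spec across FCTs has equal group means", {
  cfg <- cohort_config()
  # L-Leucine has a tiny FCT slope; zero it to create a null feature
  cfg$metabolite_spec$fct_slope[cfg$metabolite_spec$metabolite == "L-Leucine"] <- 0
  d1 <- vapply(1:2000, function(s)
    draw_metabolome(1L, "control", cfg, seed = s)[["L-Leucine"]], 1)
  d5 <- vapply(2001:4000, function(s)
    draw_metabolome(5L, "control", cfg, seed = s)[["L-Leucine"]], 1)
  expect_equal(mean(log(d1)), mean(log(d5)), tolerance = 0.05)
})

test_that("cohort TSV round-trips through the readers", {
  co <- small_cohort(n_infants = 6L, seed = 8L)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  counts <- read_count_table(file.path(dir, "counts.tsv"))
  expect_equal(unclass(counts)[, ], unclass(co$counts)[, ],
               ignore_attr = TRUE)
  meta <- read_sample_table(file.path(dir, "metadata.tsv"))
  expect_equal(meta$sample_id, co$metadata$sample_id)
  mtb <- read_feature_table(file.path(dir, "metabolites.tsv"))
  expect_equal(dim(mtb), dim(co$metabolites))
})
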