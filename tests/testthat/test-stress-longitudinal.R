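test_that("stress score is rank-based and centred", {
  set.seed(20)
  expr <- matrix(rnorm(8 * 30, 8, 2), 8, 30,
                 dimnames = list(c(STRESS_PANEL_DEFAULT, "X1", "X2"),
                                 sprintf("s%02d", 1:30)))
  sc <- stress_score(expr)
  expect_s3_class(sc, "uev_scores")
  expect_equal(mean(sc$score), 0, tolerance = 1e-8)
  # monotone per-gene transform leaves scores identical
  expr2 <- expr
  expr2[STRESS_PANEL_DEFAULT, ] <- exp(expr2[STRESS_PANEL_DEFAULT, ] / 3)
  expect_equal(stress_score(expr2)$score, sc$score)
  # quartiles each hold n/4 +/- 1 under distinct scores
  expect_true(all(abs(table(sc$quartile) - 30 / 4) <= 1))
  expect_equal(sum(sc$band == "low"), sum(sc$quartile == "Q0_25"))
  expect_error(stress_score(expr[, 1:2]), ">= 3 samples")
  expect_error(stress_score(expr, panel = "GPX3"), ">= 2 genes")
  expect_error(stress_score(expr, panel = c("GPX3", "NOPE")), "absent")
})

test_that("planted group effects order the score macro > micro > normo", {
  co <- generate_cohort(sim_config(seed = 31))
  lcpm <- log2_cpm(co$counts, tmm_factors(co$counts))
  sc <- stress_score(lcpm)
  d <- dplyr::inner_join(sc, co$meta, by = "sample_id")
  med <- tapply(d$score, d$group, median)
  expect_true(med["normo"] < med["micro"] && med["micro"] < med["macro"])
  kw <- compare_score_groups(d)
  expect_lt(kw$p_value, 0.05)
})

test_that("group comparisons: Mann-Whitney and degenerate inputs", {
  set.seed(9)
  d <- tibble::tibble(score = c(rnorm(10), rnorm(10) + 3),
                      group = rep(c("a", "b"), each = 10))
  mw <- compare_score_groups(d, test = "mann_whitney")
  expect_lt(mw$p_value, 0.001)
  expect_error(compare_score_groups(d[d$group == "a", ]), ">= 2 groups")
  d3 <- tibble::tibble(score = rnorm(9), group = rep(c("a", "b", "c"), 3))
  expect_error(compare_score_groups(d3, test = "mann_whitney"), "exactly 2")
})

test_that("label-permuted scores give a uniform null", {
  set.seed(101)
  pvals <- replicate(40, {
    d <- tibble::tibble(score = rnorm(30),
                        group = sample(rep(c("a", "b", "c"), 10)))
    compare_score_groups(d)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("clinical correlations use INT + Spearman", {
  set.seed(30)
  clin <- tibble::tibble(sample_id = sprintf("s%02d", 1:40),
                         hba1c = rnorm(40, 8, 1), sbp = rnorm(40, 135, 10))
  feat <- tibble::tibble(sample_id = clin$sample_id, score = clin$hba1c)
  res <- clinical_correlation(feat, clin)
  expect_equal(res$rho[res$variable == "hba1c"], 1.0)
  # independent noise: small rho
  feat2 <- tibble::tibble(sample_id = clin$sample_id, score = rnorm(40))
  res2 <- clinical_correlation(feat2, clin)
  expect_lt(max(abs(res2$rho)), 0.45)
  expect_error(clinical_correlation(
    tibble::tibble(sample_id = clin$sample_id, score = rep(1, 40)), clin),
    "constant")
})

test_that("generator coupling yields a positive score-HbA1c correlation", {
  co <- generate_cohort(sim_config(seed = 77))
  lcpm <- log2_cpm(co$counts, tmm_factors(co$counts))
  sc <- stress_score(lcpm)
  res <- clinical_correlation(
    dplyr::select(sc, "sample_id", "score"),
    dplyr::select(co$meta, "sample_id", "hba1c"))
  expect_gt(res$rho, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("CKD-EPI equation reproduces worked values and shape", {
  expect_equal(ckd_epi_egfr(0.7, 50, "female"), 101.0, tolerance = 0.005)
  # age -> 0 boundary for a man at the kappa knot: 141 x 1 x 1
  expect_equal(ckd_epi_egfr(0.9, 1e-9, "male"), 141, tolerance = 1e-4)
  # continuity at Scr = kappa
  eps <- 1e-9
  expect_equal(ckd_epi_egfr(0.7 - eps, 60, "female"),
               ckd_epi_egfr(0.7 + eps, 60, "female"), tolerance = 1e-6)
  # strictly decreasing in creatinine and age
  scr <- seq(0.4, 3, by = 0.1)
  expect_true(all(diff(ckd_epi_egfr(scr, 50, "male")) < 0))
  ages <- seq(20, 80, 5)
  expect_true(all(diff(ckd_epi_egfr(1, ages, "male")) < 0))
  # umol/L auto-conversion
  expect_warning(e1 <- ckd_epi_egfr(88.4, 50, "male"), "umol/L")
  expect_equal(e1, ckd_epi_egfr(1.0, 50, "male"))
  expect_equal(ckd_epi_egfr(88.4, 50, "male", unit = "umol_l"),
               ckd_epi_egfr(1.0, 50, "male"))
  expect_error(ckd_epi_egfr(-1, 50, "male"), "positive")
  # generator's inverse is consistent with the forward equation
  scr2 <- uevstress:::creatinine_from_egfr(c(40, 90, 120), 55, "male")
  expect_equal(ckd_epi_egfr(scr2, 55, "male"), c(40, 90, 120),
               tolerance = 1e-6)
})

test_that("annual eGFR means average within calendar years", {
  lt <- tibble::tibble(
    person_id = c("P1", "P1", "P1", "P2"),
    date = as.Date(c("2010-03-01", "2010-09-15", "2011-01-02", "2012-06-01")),
    egfr = c(80, 90, 70, 55))
  am <- annual_egfr_means(lt)
  expect_equal(am$egfr_mean[am$person_id == "P1" & am$year == 2010], 85)
  expect_equal(am$egfr_mean[am$person_id == "P1" & am$year == 2011], 70)
  expect_equal(am$egfr_mean[am$person_id == "P2"], 55)
  expect_equal(nrow(am), 3)
})

test_that("group slopes: exact lines, constants, and offset invariance", {
  yrs <- 2004:2018
  mk <- function(person, slope, start) {
    tibble::tibble(person_id = person, year = yrs,
                   egfr_mean = start + slope * (yrs - 2004), n_visits = 1)
  }
  annual <- dplyr::bind_rows(mk("P1", -1.55, 95), mk("P2", -1.55, 90))
  groups <- tibble::tibble(person_id = c("P1", "P2"), group = "g")
  gs <- group_slope(annual, groups)
  expect_equal(gs$slope, -1.55, tolerance = 1e-10)
  expect_equal(gs$se, 0)
  pp <- tidy(gs, per_person = TRUE)
  expect_equal(pp$slope, c(-1.55, -1.55), tolerance = 1e-10)
  # constant trajectory
  gs0 <- group_slope(dplyr::mutate(annual, egfr_mean = 80), groups)
  expect_equal(gs0$slope, 0)
  # adding a constant offset leaves the slope unchanged
  gs2 <- group_slope(dplyr::mutate(annual, egfr_mean = egfr_mean + 7), groups)
  expect_equal(gs2$slope, gs$slope)
  # a person with too few years is excluded
  short <- dplyr::bind_rows(annual, mk("P3", -5, 60)[1:3, ])
  gs3 <- group_slope(short, dplyr::bind_rows(
    groups, tibble::tibble(person_id = "P3", group = "g")))
  expect_equal(nrow(tidy(gs3, per_person = TRUE)), 2)
  expect_error(group_slope(annual[1, ], groups), "enough annual")
})

test_that("slope recovery on noisy 15-year trajectories", {
  hits <- vapply(1:15, function(s) {
    cfg <- sim_config(
      n_per_group = c(normo = 15), n_genes = 30,
      de_genes = tibble::tibble(gene = character(0), lfc_macro = numeric(0),
                                lfc_micro = numeric(0)),
      slope_model = list(base_slope = -1, stress_slope_effect = 0,
                         hyperfiltration_offset = 0, slope_noise_sd = 0,
                         visit_noise_sd = 2),
      dropout_rate = 0, seed = 400 + s)
    co <- generate_cohort(cfg)
    am <- annual_egfr_means(co$longitudinal)
    gs <- group_slope(am, tibble::tibble(person_id = co$meta$person_id,
                                         group = "all"))
    abs(gs$slope - (-1)) <= 2 * gs$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("CKD staging follows the two-low-annual-means rule", {
  mk <- function(vals) tibble::tibble(person_id = "P", year = seq_along(vals) + 2003,
                                      egfr_mean = vals, n_visits = 1)
  expect_equal(ckd_stage(mk(c(55, 58, 70, 75, 80, 82)))$stage, "stage_3_5")
  expect_equal(ckd_stage(mk(c(55, 70, 75, 80, 82, 90)))$stage, "stage_1_2")
  expect_equal(ckd_stage(mk(c(55, 52, 58)))$stage, "insufficient_data")
  multi <- dplyr::bind_rows(
    dplyr::mutate(mk(c(55, 58, 70, 75, 80, 82)), person_id = "A"),
    dplyr::mutate(mk(rep(90, 8)), person_id = "B"))
  st <- ckd_stage(multi)
  expect_equal(st$stage[st$person_id == "A"], "stage_3_5")
  expect_equal(st$stage[st$person_id == "B"], "stage_1_2")
})

test_that("ROC AUC equals the Mann-Whitney rank formulation", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1.0)
  # worked enumeration: 2 concordant, 2 discordant of 4 pairs
  expect_equal(roc_auc(c(2, 1, 3, 4), c(0, 1, 0, 1))$auc, 0.5)
  # label flip symmetry
  set.seed(14)
  s <- rnorm(30); l <- rbinom(30, 1, 0.5)
  if (sum(l) %in% c(0, 30)) l[1] <- 1 - l[1]
  expect_equal(roc_auc(s, l)$auc, 1 - roc_auc(s, 1 - l)$auc)
  # identity with wilcox.test U statistic
  u <- unname(wilcox.test(s[l == 1], s[l == 0], exact = FALSE)$statistic)
  expect_equal(roc_auc(s, l)$auc, u / (sum(l) * sum(1 - l)))
  # ties counted 0.5
  expect_equal(roc_auc(c(1, 1), c(0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # curve spans (0,0) to (1,1)
  rc <- roc_auc(s, l)$curve
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(max(rc$fpr), max(rc$tpr)), c(1, 1))
})

test_that("adjusted slope regression recovers a planted coefficient", {
  set.seed(55)
  n <- 120
  d <- tibble::tibble(
    score = rnorm(n), dbp = rnorm(n, 80, 9), hba1c = rnorm(n, 8, 1),
    sbp = rnorm(n, 135, 15), egfr_baseline = rnorm(n, 90, 10))
  d$slope <- -0.4 * d$score + rnorm(n, 0, 0.8)
  fit <- adjusted_slope_regression(d)
  row <- tidy(fit)[tidy(fit)$term == "score", ]
  # INT-standardized scale: planted beta in sd units
  beta_expected <- -0.4 / sd(d$slope)
  expect_lt(abs(row$estimate - beta_expected), 2 * row$se)
  expect_lt(row$p_value, 0.001)
  expect_false(glance(fit)$ridged)
  # duplicated predictor triggers the collinearity guard
  d$dup <- d$score
  expect_warning(
    fit2 <- adjusted_slope_regression(
      d, predictors = c("score", "dup", "dbp")),
    "collinear")
  expect_true(glance(fit2)$ridged)
  expect_error(adjusted_slope_regression(d[1:5, ]), "exceed")
})

test_that("pure-noise slopes leave the score coefficient null", {
  pv <- vapply(1:20, function(s) {
    set.seed(600 + s)
    n <- 60
    d <- tibble::tibble(
      score = rnorm(n), dbp = rnorm(n), hba1c = rnorm(n), sbp = rnorm(n),
      egfr_baseline = rnorm(n), slope = rnorm(n))
    fit <- adjusted_slope_regression(d)
    fit$p_value[fit$term == "score"]
  }, numeric(1))
  expect_lte(mean(pv < 0.05), 0.2)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("albuminuria classification implements all three rule sets", {
  # FinnDiane 24h AER, 2 of last 3 collections
  m <- tibble::tibble(person_id = rep(c("A", "B", "C"), each = 3),
                      visit = rep(1:3, 3),
                      aer = c(150, 140, 20,      # 2/3 micro
                              400, 410, 25,      # 2/3 macro
                              10, 12, 320))      # single macro -> normo
  cls <- classify_albuminuria(m, "finndiane_24h")
  expect_equal(as.character(cls$albuminuria), c("micro", "macro", "normo"))
  # boundary: AER exactly 30 and 300 fall in the closed micro interval
  mb <- tibble::tibble(person_id = c("D", "D", "E", "E"), visit = c(1, 2, 1, 2),
                       aer = c(30, 30, 300, 300))
  expect_equal(as.character(classify_albuminuria(mb, "finndiane_24h")$albuminuria),
               c("micro", "micro"))
  # DIREVA: last-visit macro by ACR, normo needs all visits clean
  md <- tibble::tibble(person_id = rep(c("F", "G"), each = 2), visit = rep(1:2, 2),
                       aer = c(10, 10, 10, 10), acr = c(2.0, 2.0, 2.0, 40))
  cd <- classify_albuminuria(md, "direva_on")
  expect_equal(as.character(cd$albuminuria), c("normo", "macro"))
  # iBEAt KDIGO, sex-specific thresholds
  mi <- tibble::tibble(person_id = c("H", "I"), visit = 1, acr = c(30, 30))
  sx <- tibble::tibble(person_id = c("H", "I"), sex = c("male", "female"))
  ci <- classify_albuminuria(mi, "ibeat_kdigo", sex = sx)
  expect_equal(as.character(ci$albuminuria), c("macro", "micro"))
  expect_error(classify_albuminuria(mi, "ibeat_kdigo"), "sex")
  expect_error(classify_albuminuria(md[, c("person_id", "visit")], "direva_on"),
               "needs aer")
})

test_that("stress quartiles separate eGFR decline end-to-end", {
  ok <- vapply(1:10, function(s) {
    co <- generate_cohort(sim_config(
      n_per_group = c(normo = 20, micro = 20, macro = 20),
      n_genes = 400, seed = 700 + s))
    lcpm <- log2_cpm(co$counts[robust_gene_set(co$counts), ],
                     tmm_factors(co$counts))
    sc <- stress_score(lcpm)
    d <- dplyr::inner_join(sc, co$meta, by = "sample_id")
    am <- annual_egfr_means(co$longitudinal)
    gs <- group_slope(am, dplyr::select(d, "person_id", group = "quartile"))
    gs$slope[gs$group == "Q0_25"] > gs$slope[gs$group == "Q75_100"]
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
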