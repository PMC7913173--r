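#' Synthetic cohort shaped like a prenatal PBDE study
#'
#' Generates a fully synthetic stand-in for a restricted autism-risk cohort:
#' five log-normal serum PBDE congener measures (four mutually highly
#' correlated on the log scale, the fifth — PBDE-153 — only weakly correlated
#' with the rest), a continuous z-scored social-responsiveness outcome, a
#' binary diagnosis outcome calibrated to a case fraction of roughly 42/166,
#' and the usual confounder set (maternal age, ordinal family income, 5-level
#' race/ethnicity, 4-level study site, child sex, gestational age). Exposure
#' values falling below a per-congener limit of detection (set at the
#' `below_lod_fraction` empirical quantile) are flagged in `below_lod_*`
#' columns, and the LODs are attached as `attr(, "lod")`, ready for
#' [impute_below_lod()] / [bws_preprocess()].
#'
#' All values are simulated; no study data enters this function.
#'
#' @param seed Integer seed.
#' @param n Cohort size.
#' @param case_fraction Target marginal probability of the binary outcome.
#' @param below_lod_fraction Fraction of each congener's values flagged as
#'   below the limit of detection.
#' @return A tibble of `n` rows with attributes `lod` (named vector) and
#'   `truth` (generating parameters).
#' @examples
#' cohort <- make_earli_like_cohort(seed = 1)
#' cor(log(cohort$pbde47), log(cohort$pbde99))
#' @export
make_earli_like_cohort <- function(seed = 1, n = 166,
                                   case_fraction = 42 / 166,
                                   below_lod_fraction = 0.05) {
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  congeners <- c("pbde28", "pbde47", "pbde99", "pbde100", "pbde153")
  R <- matrix(0.85, 5, 5)
  R[5, ] <- R[, 5] <- 0.30
  diag(R) <- 1
  log_mu <- c(-1.0, 1.6, 0.3, 0.0, 0.4)   # log ng/g levels, congener-specific
  log_sd <- c(0.9, 1.0, 1.0, 0.95, 0.8)
  Zr <- matrix(rnorm(n * 5), n, 5) %*% chol(R)
  logX <- sweep(sweep(Zr, 2, log_sd, `*`), 2, log_mu, `+`)
  X <- exp(logX)
  colnames(X) <- congeners

  lod <- vapply(congeners, function(j)
    unname(quantile(X[, j], below_lod_fraction)), numeric(1))
  below <- sweep(X, 2, lod, `<`)
  colnames(below) <- paste0("below_lod_", congeners)

  maternal_age <- round(rnorm(n, 34, 5), 1)
  gestational_age <- round(pmin(pmax(rnorm(n, 38.7, 2.1), 26), 42), 1)
  income <- sample(1:8, n, replace = TRUE,
                   prob = c(0.05, 0.02, 0.04, 0.14, 0.15, 0.16, 0.31, 0.07))
  race <- sample(c("white_nh", "white_hisp", "black", "asian", "other"),
                 n, replace = TRUE, prob = c(0.55, 0.08, 0.11, 0.13, 0.13))
  site <- sample(c("drexel", "jhu", "kaiser", "ucdavis"),
                 n, replace = TRUE, prob = c(0.24, 0.25, 0.29, 0.22))
  male <- rbinom(n, 1, 0.56)

  # generating model: weighted sum of z-scored log exposures, modest effect
  true_w <- c(0.25, 0.25, 0.2, 0.2, 0.1)
  zlog <- scale(logX)
  mix <- drop(zlog %*% true_w)
  srs_raw <- 0.25 * mix + 0.4 * male + rnorm(n, 0, 0.95)
  srs_z <- zscore(srs_raw)
  eta_bin <- 0.35 * mix + 0.9 * male
  icpt <- stats::qlogis(case_fraction) - mean(eta_bin)
  asd <- rbinom(n, 1, stats::plogis(icpt + eta_bin))

  out <- dplyr::bind_cols(
    tibble::tibble(asd = asd, srs_z = srs_z,
                   maternal_age = maternal_age,
                   gestational_age = gestational_age,
                   income = income, race = race, site = site, male = male),
    tibble::as_tibble(X), tibble::as_tibble(below))
  attr(out, "lod") <- lod
  attr(out, "truth") <- list(weights = true_w, theta_srs = 0.25,
                             theta_asd = 0.35)
  out
}
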