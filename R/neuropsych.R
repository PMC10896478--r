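#' Cognitive test battery
#'
#' Couples raw per-subject test scores with a test catalogue assigning every
#' test to exactly one cognitive domain and flagging its direction: timed
#' tests (trail making, Stroop times) have `higher_is_better = FALSE` and are
#' sign-flipped after z-scoring so that larger composite values always mean
#' better performance.
#'
#' @param scores data.frame/matrix of raw scores, one row per subject, one
#'   column per test (column names must appear in the catalogue).
#' @param catalogue data.frame with columns `test`, `domain`,
#'   `higher_is_better`; default [default_test_catalogue()].
#' @return Object of class `cognitive_battery`.
#' @export
cognitive_battery <- function(scores, catalogue = default_test_catalogue()) {
  scores <- as.data.frame(scores)
  req <- c("test", "domain", "higher_is_better")
  if (!all(req %in% names(catalogue)))
    stop("catalogue needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(catalogue$test))
    stop("each test must be assigned to exactly one domain")
  unknown <- setdiff(names(scores), catalogue$test)
  if (length(unknown))
    stop("tests missing from the catalogue: ", paste(unknown, collapse = ", "))
  structure(list(scores = scores,
                 catalogue = catalogue[catalogue$test %in% names(scores), ]),
            class = "cognitive_battery")
}

#' Default cognitive test catalogue
#'
#' Concise battery covering episodic memory (delayed-recall tests),
#' visuospatial function, executive function, information processing speed
#' and the MMSE as global cognition; timed tests carry
#' `higher_is_better = FALSE`. Also shipped as
#' `inst/extdata/test_catalogue.yaml`.
#'
#' @export
default_test_catalogue <- function() {
  path <- system.file("extdata", "test_catalogue.yaml", package = "fcsconn")
  y <- yaml::read_yaml(path)
  do.call(rbind, lapply(y$tests, function(t)
    data.frame(test = t$test, domain = t$domain,
               higher_is_better = isTRUE(t$higher_is_better))))
}

#' Composite cognitive-domain Z-scores
#'
#' Each test is z-scored against the reference subjects' mean and SD; tests
#' where lower raw scores mean better performance are sign-flipped after
#' z-scoring; a subject's domain composite is the mean of the signed
#' z-scores of that domain's tests. Missing tests are excluded from the
#' subject's mean (and reported in the `"n_missing"` attribute).
#'
#' @param battery a [cognitive_battery()].
#' @param reference indices (or logical) of the reference subjects, usually
#'   the healthy-control group; needs >= 2 subjects and nonzero SD per test.
#' @return data.frame of composites, one row per subject, one column per
#'   domain.
#' @export
composite_z <- function(battery, reference) {
  stopifnot(inherits(battery, "cognitive_battery"))
  S <- battery$scores
  ref <- S[reference, , drop = FALSE]
  if (nrow(ref) < 2L) stop("reference subset needs at least 2 subjects")
  Z <- S
  for (tn in names(S)) {
    mu <- mean(ref[[tn]], na.rm = TRUE)
    sdv <- stats::sd(ref[[tn]], na.rm = TRUE)
    if (!is.finite(sdv) || sdv < 1e-12)
      stop("zero reference SD for test '", tn, "'")
    z <- (S[[tn]] - mu) / sdv
    hib <- battery$catalogue$higher_is_better[match(tn, battery$catalogue$test)]
    Z[[tn]] <- if (hib) z else -z
  }
  domains <- unique(battery$catalogue$domain)
  out <- data.frame(row.names = seq_len(nrow(S)))
  n_missing <- 0L
  for (d in domains) {
    tests <- battery$catalogue$test[battery$catalogue$domain == d]
    zm <- as.matrix(Z[, tests, drop = FALSE])
    n_missing <- n_missing + sum(is.na(zm))
    out[[d]] <- rowMeans(zm, na.rm = TRUE)
  }
  attr(out, "n_missing") <- n_missing
  out
}

#' Pooled-variance two-sample t-test
#'
#' Independent two-sample t-test with pooled variance (two-sided), as used
#' for group comparisons of continuous demographics.
#'
#' @param x,y numeric samples (>= 2 each).
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per group")
  if (stats::var(c(x - mean(x), y - mean(y))) < 1e-300)
    stop("zero pooled variance")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square WITHOUT continuity correction (df = 1, two-sided);
#' the Yates correction can be enabled but is off by default.
#'
#' @param table 2x2 matrix of nonnegative counts with all marginals > 0.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return List with `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0))
    stop("table must be a 2x2 matrix of nonnegative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in the 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' ANCOVA on a cognitive composite
#'
#' Group effect on a domain composite (or MMSE) adjusted for age and years
#' of education: fits `score ~ group + age + education` and returns the
#' group F statistic (equal to the squared group t) and its p-value. With
#' `covariates = NULL` this reduces exactly to the squared pooled-variance
#' two-sample t-test.
#'
#' @param score numeric vector, one value per subject.
#' @param group 0/1 indicator or patient/control labels.
#' @param age,education covariate vectors; pass `NULL` to omit.
#' @return List with `F`, `df1`, `df2`, `p`, and the signed group `t`.
#' @export
ancova_domain <- function(score, group, age = NULL, education = NULL) {
  grp <- if (is.numeric(group)) group else as.integer(group %in% c("patient", "1", 1, TRUE))
  X <- cbind(intercept = 1, group = grp)
  if (!is.null(age)) X <- cbind(X, age = age)
  if (!is.null(education)) X <- cbind(X, education = education)
  fit <- fit_voxelwise_glm(matrix(score, ncol = 1), X, "group")
  Fv <- fit$t^2
  list(F = Fv, df1 = 1L, df2 = fit$df,
       p = stats::pf(Fv, 1, fit$df, lower.tail = FALSE), t = fit$t)
}

#' Cohort demographic and cognitive summary table
#'
#' Per-variable group means (SD) with the matching test: pooled-variance
#' t-test for age and education, chi-square (no continuity correction) for
#' sex, ANCOVA adjusted for age and education for MMSE and the four domain
#' composites.
#'
#' @param tab cohort table as returned by [simulate_cohort_table()].
#' @return data.frame with variable, patient and control summaries, test
#'   name and p-value.
#' @export
cohort_summary <- function(tab) {
  pat <- tab$group == "patient"
  msd <- function(v, g) sprintf("%.2f ± %.2f", mean(v[g]), stats::sd(v[g]))
  rows <- list()
  for (v in c("age", "education")) {
    tt <- two_sample_t(tab[[v]][pat], tab[[v]][!pat])
    rows[[v]] <- data.frame(variable = v, patients = msd(tab[[v]], pat),
                            controls = msd(tab[[v]], !pat),
                            test = "t", p = tt$p)
  }
  sex_tab <- rbind(c(sum(tab$sex[pat] == 1), sum(tab$sex[pat] == 0)),
                   c(sum(tab$sex[!pat] == 1), sum(tab$sex[!pat] == 0)))
  cs <- chi_square_2x2(sex_tab)
  rows$sex <- data.frame(variable = "sex (M/F)",
                         patients = paste0(sex_tab[1, 1], "/", sex_tab[1, 2]),
                         controls = paste0(sex_tab[2, 1], "/", sex_tab[2, 2]),
                         test = "chi2", p = cs$p)
  for (v in c("mmse", "episodic_memory", "executive_function",
              "information_processing_speed", "visuospatial_function")) {
    if (!v %in% names(tab)) next
    an <- ancova_domain(tab[[v]], as.integer(pat), tab$age, tab$education)
    rows[[v]] <- data.frame(variable = v, patients = msd(tab[[v]], pat),
                            controls = msd(tab[[v]], !pat),
                            test = "ancova", p = an$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
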