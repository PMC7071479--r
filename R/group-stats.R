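#' Shapiro-Wilk normality gate
#'
#' The analysis plan routes data through a normality check: groups
#' passing it (and an equal-variance check) are compared with t-tests;
#' data failing it (as the fluorescence proportions do) are analyzed
#' with rank-based Spearman correlation instead.
#'
#' @param values Numeric vector, `3 <= n <= 5000`.
#' @param alpha Significance level of the gate (default 0.05).
#' @return List: `statistic` (W), `p_value`, `normal` (logical,
#'   `p > alpha`), `n`.
#' @export
shapiro_gate <- function(values, alpha = 0.05) {
  if (!is.numeric(values) || anyNA(values))
    stop_fq("'values' must be numeric without NA")
  if (length(values) < 3)
    stop_fq("Shapiro-Wilk needs at least 3 observations")
  if (diff(range(values)) == 0)
    stop_fq("degenerate input: all values identical, normality undefined")
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       normal = sw$p.value > alpha, n = length(values))
}

# the six pairwise comparisons of the design, in reporting order
.ttest_pairs <- matrix(c(
  "early_MFG", "early_aHPC",
  "early_MFG", "late_MFG",
  "early_MFG", "late_aHPC",
  "late_MFG",  "early_aHPC",
  "late_MFG",  "late_aHPC",
  "early_aHPC", "late_aHPC"), ncol = 2, byrow = TRUE)

#' The six pairwise t-tests of the four-group design
#'
#' Two-sample, two-sided, equal-variance t-tests on case mean scores
#' for each of the six group pairs: control (early MFG) against each
#' NFT-affected group, and the NFT-affected groups among themselves.
#' No multiplicity correction is applied by default (matching the
#' original plan); `p_adjust = "holm"` is available.
#'
#' @param case_table Data frame with columns `mean_score` and `group`
#'   (labels as in [group_levels()]); every group needs >= 2 cases.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()]
#'   method.
#' @return Data frame, one row per comparison: `group1`, `group2`,
#'   `t`, `df`, `p_value`, `p_adjusted`, `mean1`, `mean2`.
#' @export
pairwise_ttests <- function(case_table, p_adjust = "none") {
  stopifnot(is.data.frame(case_table),
            all(c("mean_score", "group") %in% names(case_table)))
  split_means <- split(case_table$mean_score, case_table$group)
  missing <- setdiff(.group_levels, names(split_means))
  if (length(missing))
    stop_fq(sprintf("group(s) absent: %s", paste(missing, collapse = ", ")))
  small <- names(split_means)[vapply(split_means, length, 1L) < 2]
  if (length(small))
    stop_fq(sprintf("group(s) too small for a t-test: %s",
                    paste(small, collapse = ", ")))
  out <- apply(.ttest_pairs, 1, function(pair) {
    a <- split_means[[pair[1]]]
    b <- split_means[[pair[2]]]
    tt <- t.test(a, b, var.equal = TRUE)
    data.frame(group1 = pair[1], group2 = pair[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, mean1 = mean(a), mean2 = mean(b))
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out[c("group1", "group2", "t", "df", "p_value", "p_adjusted",
        "mean1", "mean2")]
}

#' Count of APOE epsilon-4 alleles
#'
#' Parses genotype strings such as `"e3/e4"`, `"ε3–ε4"` or `"e4/e4"`
#' into the number of ε4 alleles (0, 1 or 2), the numeric coding used
#' as the ANCOVA covariate. Empty strings, `"-"` and `NA` yield `NA`.
#'
#' @param genotype Character vector of APOE genotypes.
#' @return Integer vector of ε4 counts with `NA` for missing.
#' @export
apoe_e4_count <- function(genotype) {
  g <- as.character(genotype)
  missing <- is.na(g) | trimws(g) %in% c("", "-", "NA")
  n4 <- vapply(g, function(s) {
    if (is.na(s)) return(0L)
    as.integer(sum(gregexpr("4", s)[[1]] > 0))
  }, 1L, USE.NAMES = FALSE)
  bad <- !missing & (n4 > 2L | !grepl("[234]", g))
  if (any(bad))
    stop_fq(sprintf("unparseable APOE genotype: %s",
                    paste(unique(g[bad]), collapse = ", ")))
  ifelse(missing, NA_integer_, n4)
}

#' ANCOVA of case scores with clinical covariates
#'
#' Linear-model analysis of covariance on the case-level mean scores:
#' fixed factors are neuropathological stage and brain region,
#' covariates are age, final MMSE and the APOE ε4-allele count. Cases
#' with a missing covariate are dropped listwise (their ids are
#' reported in a message). Per-term F-tests are Type II
#' ([car::Anova()]), which coincides with Type III for covariates not
#' involved in interactions.
#'
#' @param cases Data frame with columns `mean_score`, `stage`,
#'   `region`, `age`, `final_mmse` and `apoe` (genotype string) or
#'   `apoe_e4` (numeric).
#' @return List: `table` (data frame `term`, `df`, `F`, `p_value`,
#'   `note`), `n_used`, `dropped_cases`, `fit` (the `lm` object).
#'   Covariates constant across the retained cases are flagged
#'   inestimable rather than dropped silently; the same applies to any
#'   aliased (rank-deficient) term.
#' @export
ancova_covariates <- function(cases) {
  need <- c("mean_score", "stage", "region", "age", "final_mmse")
  miss <- setdiff(need, names(cases))
  if (length(miss))
    stop_fq(sprintf("'cases' lacks column(s): %s",
                    paste(miss, collapse = ", ")))
  if (!"apoe_e4" %in% names(cases)) {
    if (!"apoe" %in% names(cases))
      stop_fq("'cases' needs an 'apoe' or 'apoe_e4' column")
    cases$apoe_e4 <- apoe_e4_count(cases$apoe)
  }
  if (!"case_id" %in% names(cases))
    cases$case_id <- sprintf("case%02d", seq_len(nrow(cases)))
  covars <- c("age", "final_mmse", "apoe_e4")
  complete <- stats::complete.cases(cases[c("mean_score", "stage", "region",
                                            covars)])
  dropped <- cases$case_id[!complete]
  if (length(dropped))
    message(sprintf("ancova: dropped case(s) with missing covariates: %s",
                    paste(dropped, collapse = ", ")))
  d <- cases[complete, , drop = FALSE]
  if (nrow(d) < 7)
    stop_fq("too few complete cases for the ANCOVA model")
  d$stage <- factor(d$stage, levels = c("early", "late"))
  d$region <- factor(d$region, levels = c("MFG", "aHPC"))

  constant <- covars[vapply(covars, function(v) length(unique(d[[v]])) < 2,
                            TRUE)]
  terms_used <- c("stage", "region", setdiff(covars, constant))
  fml <- stats::reformulate(terms_used, response = "mean_score")
  fit <- lm(fml, data = d)
  aliased <- names(which(is.na(coef(fit))))
  an <- car::Anova(fit, type = "II")
  tab <- data.frame(term = rownames(an), df = an$Df, F = an$`F value`,
                    p_value = an$`Pr(>F)`, note = "",
                    stringsAsFactors = FALSE)
  tab <- tab[tab$term != "Residuals", , drop = FALSE]
  if (length(constant))
    tab <- rbind(tab, data.frame(term = constant, df = NA, F = NA,
                                 p_value = NA,
                                 note = "inestimable: constant covariate"))
  if (length(aliased))
    tab$note[tab$term %in% aliased] <-
      "inestimable: aliased (rank-deficient)"
  rownames(tab) <- NULL
  list(table = tab, n_used = nrow(d), dropped_cases = dropped, fit = fit)
}

#' Spearman rank correlation with midranks and exact small-sample p
#'
#' Computes Spearman's rho as the Pearson correlation of midranks
#' (ties receive average ranks). The two-sided p-value is exact for
#' `n <= 9` — full enumeration of all `n!` permutations, valid under
#' ties — and uses the t-distribution approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise. No reporting
#' floor is applied; at `|rho| = 1` the asymptotic p underflows to 0.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, each with at
#'   least 2 distinct values.
#' @return List: `rho`, `p_value`, `n`, `method` (`"exact"` or
#'   `"asymptotic"`).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop_fq("'x' and 'y' lengths differ")
  if (anyNA(x) || anyNA(y)) stop_fq("missing values not allowed")
  n <- length(x)
  if (n < 3) stop_fq("need at least 3 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop_fq("degenerate input: a variable is constant")
  rx <- rank(x)  # midranks
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    p <- spearman_exact_p(rx, ry, rho)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "asymptotic"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# Two-sided exact permutation p for the midrank rho: enumerate all n!
# orderings of y's ranks against fixed x ranks.
spearman_exact_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- permutations_all(n)
  a <- (rx - mean(rx)) / (sd(rx) * (n - 1))
  pm <- matrix(ry[perms], nrow = nrow(perms))
  rhos <- as.vector((pm - mean(ry)) %*% a) / sd(ry)
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# All permutations of 1:n as an n! x n matrix (n <= 9).
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, m * n, n)
  for (pos in seq_len(n)) {
    block <- (pos - 1L) * m + seq_len(m)
    out[block, pos] <- n
    out[block, setdiff(seq_len(n), pos)] <- sub
  }
  out
}
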