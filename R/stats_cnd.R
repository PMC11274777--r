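## Correlation analyses and causal-network-diagram (CND) edge
## classification. The CNDs are correlational direction summaries of
## FU-vs-age effects, not formal causal inference.

#' Spearman correlation map of band powers against covariates
#'
#' Rank-correlates each (cluster, band) cell of a tidy band-power table
#' with each cohort covariate, using tie-corrected ranks and the two-sided
#' t approximation for p values. Cells with a constant variable are
#' reported as missing (NA), not zero.
#'
#' @param table tidy data.frame from [band_power_table()] (columns
#'   `participant`, `cluster`, `band`, and the measure column).
#' @param cohort data.frame with a `participant` id column and covariate
#'   columns (e.g. from [generate_cohort()]).
#' @param covariates covariate column names to correlate.
#' @param measure which power column to use, `"relative"` or `"absolute"`.
#' @return data.frame with `cluster`, `band`, `covariate`, `rho`, `p`, `n`.
#' @export
spearman_map <- function(table, cohort,
                         covariates = c("age", "psych", "phys", "stress"),
                         measure = c("relative", "absolute")) {
  measure <- match.arg(measure)
  stopifnot(all(c("participant", "cluster", "band", measure) %in% names(table)),
            "participant" %in% names(cohort),
            all(covariates %in% names(cohort)))
  cells <- unique(table[, c("cluster", "band")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- table[table$cluster == cells$cluster[i] & table$band == cells$band[i], ]
    m <- match(sub$participant, cohort$participant)
    for (cv in covariates) {
      x <- sub[[measure]]
      y <- cohort[[cv]][m]
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        rho <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
        )
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cells$cluster[i], band = cells$band[i], covariate = cv,
        rho = rho, p = p, n = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of FU entries with age
#'
#' For every ordered source pair (A, B), correlates the participants'
#' mean follow-up counts FU(A -> B) with their age, returning grids of
#' Pearson r and two-sided p values (t distribution, n - 2 df). Entries
#' with zero variance across participants are missing.
#'
#' @param fu_list list of `fu_matrix` objects, one per participant.
#' @param ages numeric vector of ages, aligned with `fu_list`.
#' @return list with `r` and `p` (n x n matrices) and `n` participants.
#' @export
pearson_fu_age <- function(fu_list, ages) {
  stopifnot(length(fu_list) == length(ages))
  np <- length(fu_list)
  if (np < 3) stop("need at least 3 participants")
  nsrc <- nrow(fu_list[[1]])
  flat <- vapply(fu_list, function(m) as.vector(unclass(m)), numeric(nsrc^2))
  # rows: source pairs; columns: participants
  xm <- flat - rowMeans(flat)
  y <- ages - mean(ages)
  sy <- sqrt(sum(y^2))
  sx <- sqrt(rowSums(xm^2))
  r <- as.vector(xm %*% y) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  tstat <- r * sqrt((np - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = np - 2)
  dn <- dimnames(fu_list[[1]])
  rmat <- matrix(r, nsrc, nsrc, dimnames = dn)
  pmat <- matrix(p, nsrc, nsrc, dimnames = dn)
  list(r = rmat, p = pmat, n = np)
}

#' One-sample t test against an upper bound
#'
#' Tests whether the mean of `values` lies below `bound` (one-sided,
#' lower tail), e.g. whether residual variances rank below 10%.
#'
#' @param values numeric vector (e.g. percentages).
#' @param bound the bound to test against.
#' @return list with `t`, `p`, `df`, `mean`.
#' @export
ttest_below <- function(values, bound) {
  if (length(values) < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0) {
    stop("zero variance; report the exact values instead of a t test")
  }
  ht <- stats::t.test(values, mu = bound, alternative = "less")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean = mean(values))
}

#' Classify significant FU-age correlations into network edges
#'
#' For each unordered source pair, the two directed correlations are
#' classified at level `alpha`: both significant with equal signs gives
#' one bi-directional edge; both significant with opposite signs gives two
#' uni-directional edges; exactly one significant direction gives one
#' uni-directional edge. Diagonal (self-persistence) effects are reported
#' separately, never as edges.
#'
#' @param r,p square matrices from [pearson_fu_age()].
#' @param alpha significance level in (0, 1); the conventional uncorrected
#'   0.05 by default.
#' @param p_adjust optional multiple-testing correction (a method name for
#'   [stats::p.adjust()], e.g. `"BH"`) applied to the off-diagonal p values
#'   before classification. Off by default.
#' @return a `cnd_edges` data.frame with columns `from`, `to`, `sign`,
#'   `directionality`, `r_fwd`, `p_fwd`, `r_rev`, `p_rev`; attribute
#'   `self` holds the diagonal effects, attribute `alpha` the level.
#' @export
build_cnd <- function(r, p, alpha = 0.05, p_adjust = NULL) {
  stopifnot(is.matrix(r), is.matrix(p), all(dim(r) == dim(p)),
            nrow(r) == ncol(r))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  n <- nrow(r)
  nm <- rownames(r) %||% as.character(seq_len(n))
  if (!is.null(p_adjust)) {
    off <- row(p) != col(p)
    p[off] <- stats::p.adjust(p[off], method = p_adjust)
  }
  edges <- list()
  add <- function(from, to, sign, dir, rf, pf, rr, pr) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, sign = sign, directionality = dir,
      r_fwd = rf, p_fwd = pf, r_rev = rr, p_rev = pr,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pf <- p[i, j]; pr <- p[j, i]
      sf <- !is.na(pf) && pf < alpha
      sr <- !is.na(pr) && pr < alpha
      if (sf && sr) {
        if (sign(r[i, j]) == sign(r[j, i])) {
          add(nm[i], nm[j], if (r[i, j] > 0) "+" else "-", "bi",
              r[i, j], pf, r[j, i], pr)
        } else {
          add(nm[i], nm[j], if (r[i, j] > 0) "+" else "-", "uni",
              r[i, j], pf, r[j, i], pr)
          add(nm[j], nm[i], if (r[j, i] > 0) "+" else "-", "uni",
              r[j, i], pr, r[i, j], pf)
        }
      } else if (sf) {
        add(nm[i], nm[j], if (r[i, j] > 0) "+" else "-", "uni",
            r[i, j], pf, r[j, i], pr)
      } else if (sr) {
        add(nm[j], nm[i], if (r[j, i] > 0) "+" else "-", "uni",
            r[j, i], pr, r[i, j], pf)
      }
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else data.frame(
    from = character(0), to = character(0), sign = character(0),
    directionality = character(0), r_fwd = numeric(0), p_fwd = numeric(0),
    r_rev = numeric(0), p_rev = numeric(0), stringsAsFactors = FALSE)
  self <- data.frame(source = nm, r = diag(r), p = diag(p),
                     significant = !is.na(diag(p)) & diag(p) < alpha,
                     stringsAsFactors = FALSE)
  structure(out, self = self, alpha = alpha, class = c("cnd_edges", "data.frame"))
}
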