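#' Per-wavenumber two-sample t statistics
#'
#' Pooled-variance two-sample t at every wavenumber, tumor minus normal, with
#' two-sided p from the t distribution on n1 + n2 - 2 df (Welch optional).
#' Borderline and unknown spectra are excluded.
#'
#' @param set a `raman_set` with >= 2 tumor and >= 2 normal spectra
#' @param welch use the Welch (unequal-variance) statistic
#' @return list with `axis`, `t`, `p`, `n_tumor`, `n_normal`
#' @export
tstat_per_wavenumber <- function(set, welch = FALSE) {
  g <- set$meta$label
  X <- set$intensities[g %in% c("tumor", "normal"), , drop = FALSE]
  g <- g[g %in% c("tumor", "normal")]
  n1 <- sum(g == "tumor"); n2 <- sum(g == "normal")
  if (n1 < 2L || n2 < 2L)
    stop("need >= 2 spectra per group (have ", n1, " tumor, ", n2, " normal)",
         call. = FALSE)
  ts <- .tstat_matrix(X, g == "tumor", welch = welch)
  list(axis = set$axis, t = ts$t, p = ts$p, n_tumor = n1, n_normal = n2)
}

# vectorized pooled / Welch t over columns of X; g1 logical group-1 indicator
.tstat_matrix <- function(X, g1, welch = FALSE) {
  n1 <- sum(g1); n2 <- sum(!g1)
  s1 <- colSums(X[g1, , drop = FALSE]); s2 <- colSums(X[!g1, , drop = FALSE])
  q1 <- colSums(X[g1, , drop = FALSE]^2); q2 <- colSums(X[!g1, , drop = FALSE]^2)
  m1 <- s1 / n1; m2 <- s2 / n2
  ss1 <- pmax(q1 - n1 * m1^2, 0); ss2 <- pmax(q2 - n2 * m2^2, 0)
  d <- m1 - m2
  if (welch) {
    v1 <- ss1 / (n1 - 1L); v2 <- ss2 / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
  } else {
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2L, length(d))
  }
  t <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, sign(d) * Inf))
  p <- 2 * pt(-abs(t), df)
  p[is.infinite(t)] <- 0
  list(t = t, p = p)
}

# null |t| matrix (m x K) for the given group-1 index sets (n x K logical)
.null_abs_t <- function(X, G, welch = FALSE) {
  vapply(seq_len(ncol(G)), function(k)
    abs(.tstat_matrix(X, G[, k], welch = welch)$t), numeric(ncol(X)))
}

# empirical FDR at thresholds c: mean null exceedance count / observed count
.fdr_at <- function(abs_t_obs, abs_t_null, thresholds) {
  K <- ncol(abs_t_null)
  sorted_null <- sort(as.numeric(abs_t_null))
  sorted_obs <- sort(abs_t_obs)
  vapply(thresholds, function(c) {
    n_null <- length(sorted_null) -
      findInterval(c, sorted_null, left.open = TRUE)   # count >= c (closed)
    n_obs <- length(sorted_obs) - findInterval(c, sorted_obs, left.open = TRUE)
    (n_null / K) / max(1L, n_obs)
  }, numeric(1L))
}

#' Permutation-based false discovery rate for per-wavenumber t statistics
#'
#' Group labels are permuted freely across spectra; for each observed
#' threshold c = |t_j| the FDR estimate is the permutation-mean count of null
#' |t*| >= c divided by the observed count of |t| >= c, and the q-value of
#' wavenumber j is the minimum FDR over all thresholds <= |t_j|, clipped to
#' \[0, 1\] (monotone non-increasing in |t|). When the number of distinct
#' label assignments is at most `cap` (and mode allows), all assignments are
#' enumerated; otherwise `B` assignments are sampled and the observed
#' labeling is included among them.
#'
#' @param set a `raman_set` (borderline/unknown excluded automatically)
#' @param B number of sampled permutations (sampled mode), >= 1
#' @param seed integer seed for sampled mode
#' @param mode `"auto"`, `"exhaustive"` or `"sampled"`
#' @param cap exhaustive-enumeration cap on the number of assignments
#' @param welch use Welch t statistics throughout
#' @return list of class `differential_result`: axis, t, p, q, n_tumor,
#'   n_normal, n_permutations, permutation_mode, seed
#' @export
permutation_fdr <- function(set, B = 1000L, seed = 1L,
                            mode = c("auto", "exhaustive", "sampled"),
                            cap = 10000L, welch = FALSE) {
  mode <- match.arg(mode)
  g <- set$meta$label
  keep <- g %in% c("tumor", "normal")
  X <- set$intensities[keep, , drop = FALSE]
  g <- g[keep]
  n <- length(g); n1 <- sum(g == "tumor")
  if (n1 < 2L || n - n1 < 2L)
    stop("need >= 2 spectra per group", call. = FALSE)
  n_assign <- choose(n, n1)
  if (mode == "auto")
    mode <- if (n_assign <= cap) "exhaustive" else "sampled"
  obs <- .tstat_matrix(X, g == "tumor", welch = welch)
  if (mode == "exhaustive") {
    sets <- combn(n, n1)
    G <- matrix(FALSE, n, ncol(sets))
    G[cbind(as.vector(sets),
            rep(seq_len(ncol(sets)), each = n1))] <- TRUE
    K <- ncol(G)
  } else {
    if (B < 1L) stop("B must be >= 1 in sampled mode", call. = FALSE)
    set.seed(seed)
    G <- matrix(FALSE, n, B + 1L)
    G[which(g == "tumor"), 1L] <- TRUE      # observed labeling included
    for (b in seq_len(B)) G[sample.int(n, n1), b + 1L] <- TRUE
    K <- B + 1L
  }
  null_abs <- .null_abs_t(X, G, welch = welch)
  abs_obs <- abs(obs$t)
  thr <- sort(unique(abs_obs))
  fdr <- .fdr_at(abs_obs, null_abs, thr)
  qthr <- cummin(pmin(fdr, 1))          # min over thresholds <= c, clipped
  q <- qthr[match(abs_obs, thr)]
  structure(list(axis = set$axis, t = obs$t, p = obs$p, q = q,
                 n_tumor = n1, n_normal = n - n1, n_permutations = K,
                 permutation_mode = mode, seed = as.integer(seed)),
            class = "differential_result")
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("<differential_result> %d wavenumbers, %d tumor vs %d normal, %s (%d permutations)\n",
              length(x$axis), x$n_tumor, x$n_normal, x$permutation_mode,
              x$n_permutations))
  cat(sprintf("  q < 0.05 at %d wavenumbers\n", sum(x$q < 0.05)))
  invisible(x)
}

#' Summarize differential results over band windows
#'
#' For each band-table window: the fraction of wavenumbers with q < alpha,
#' the direction of the mean t, and an `elevated` call — TRUE when at least
#' half the window's wavenumbers pass with positive (tumor > normal)
#' direction. Windows outside the result axis are skipped with a warning.
#'
#' @param result a `differential_result`
#' @param bands a [band_table()]
#' @param alpha significance level in (0, 1)
#' @return data.frame: lo, hi, assignment, n_wavenumbers, frac_significant,
#'   direction, elevated
#' @export
summarize_bands <- function(result, bands = default_band_table(), alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  rows <- lapply(seq_len(nrow(bands)), function(k) {
    inwin <- result$axis >= bands$lo[k] & result$axis <= bands$hi[k]
    if (!any(inwin)) {
      warning(sprintf("band %g-%g outside result axis; skipped",
                      bands$lo[k], bands$hi[k]))
      return(NULL)
    }
    qs <- result$q[inwin]; ts <- result$t[inwin]
    frac_pos <- mean(qs < alpha & ts > 0)
    data.frame(lo = bands$lo[k], hi = bands$hi[k],
               assignment = bands$assignment[k],
               n_wavenumbers = sum(inwin),
               frac_significant = mean(qs < alpha),
               direction = sign(mean(ts)),
               elevated = frac_pos >= 0.5,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
}
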