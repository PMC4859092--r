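#' Shrinkage t-statistics for many sinks at once
#'
#' A two-sample pooled t-test whose per-sink variance is regularized toward
#' the median pooled variance across all sinks, stabilizing inference when
#' per-sink sample sizes are small. With pooled variance `v_k`
#' (df = n_a + n_b - 2) and target `v_med = median(v)`, the shrunken variance
#' is `v*_k = lambda * v_med + (1 - lambda) * v_k` with intensity
#' `lambda = min(1, sum(var_hat(v_k)) / sum((v_k - v_med)^2))`, where
#' `var_hat(v_k) = 2 v_k^2 / df` is the normal-theory variance of the pooled
#' variance estimate. The statistic is
#' `t_k = (mean_a - mean_b) / sqrt(v*_k (1/n_a + 1/n_b))` with two-sided
#' p-values from the t distribution with `n_a + n_b - 2` degrees of freedom.
#' When all `v_k` are equal the intensity denominator vanishes, `lambda` is
#' set to 1 and the statistic reduces to the ordinary pooled two-sample t.
#'
#' @param group_a,group_b Sink x sample numeric matrices (same rows; at least
#'   2 samples each).
#' @return Data frame with columns `sink_id`, `mean_a`, `mean_b`, `t_shrink`,
#'   `p_value`, plus attributes `lambda` and `df`.
#' @export
shrinkage_t <- function(group_a, group_b) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  n_a <- ncol(group_a); n_b <- ncol(group_b)
  if (n_a < 2L || n_b < 2L) stop("each group needs at least 2 samples")
  if (nrow(group_a) != nrow(group_b)) stop("groups must share the sink set")
  df <- n_a + n_b - 2L
  m_a <- rowMeans(group_a); m_b <- rowMeans(group_b)
  s2_a <- apply(group_a, 1, var); s2_b <- apply(group_b, 1, var)
  v <- ((n_a - 1L) * s2_a + (n_b - 1L) * s2_b) / df
  v_med <- stats::median(v)
  denom <- sum((v - v_med)^2)
  lambda <- if (denom > 0) min(1, sum(2 * v^2 / df) / denom) else 1
  v_star <- lambda * v_med + (1 - lambda) * v
  se <- sqrt(v_star * (1 / n_a + 1 / n_b))
  diff <- m_a - m_b
  t_stat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df = df),
              0)
  p[t_stat == 0 & se == 0] <- 1
  out <- data.frame(sink_id = rownames(group_a) %||%
                      paste0("sink", seq_along(t_stat)),
                    mean_a = m_a, mean_b = m_b,
                    t_shrink = as.numeric(t_stat), p_value = as.numeric(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "lambda") <- lambda
  attr(out, "df") <- df
  attr(out, "v_shrunk") <- as.numeric(v_star)
  attr(out, "v_raw") <- as.numeric(v)
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; q-values are monotone
#' non-decreasing in p-value rank and stay attached to their input positions.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential PSF of a disease class versus healthy controls
#'
#' For every sink: the difference of mean log2 PSF between the disease class
#' and the healthy class (a log fold difference), its shrinkage t-statistic
#' and p-value, the BH q-value, and the significance flag
#' `p < alpha_p & q < alpha_q` (defaults 0.05 and 0.2).
#'
#' @param psf Sink x sample PSF matrix (positive), e.g. from
#'   [compute_psf_matrix()].
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @param disease_label,healthy_label Class labels to compare.
#' @param alpha_p,alpha_q Significance thresholds on p and q.
#' @return Data frame with columns `sink_id`, `pathway_id`, `delta`,
#'   `t_shrink`, `p_value`, `q_value`, `significant`.
#' @export
differential_psf <- function(psf, sheet, disease_label, healthy_label,
                             alpha_p = 0.05, alpha_q = 0.2) {
  sheet <- read_sample_sheet(sheet)
  cols_of <- function(lab) {
    s <- intersect(sheet$sample_id[sheet$class_label == lab], colnames(psf))
    if (length(s) == 0L) stop("class not present in PSF matrix: ", lab)
    s
  }
  a <- log2(psf[, cols_of(disease_label), drop = FALSE])
  b <- log2(psf[, cols_of(healthy_label), drop = FALSE])
  st <- shrinkage_t(a, b)
  q <- fdr_adjust(st$p_value)
  map <- attr(psf, "sink_map")
  pathway_id <- if (!is.null(map)) {
    map$pathway_id[match(rownames(psf), map$sink_id)]
  } else sub(":[^:]*$", "", rownames(psf))
  data.frame(sink_id = rownames(psf), pathway_id = pathway_id,
             delta = st$mean_a - st$mean_b,
             t_shrink = st$t_shrink, p_value = st$p_value, q_value = q,
             significant = st$p_value < alpha_p & q < alpha_q,
             row.names = NULL, stringsAsFactors = FALSE)
}
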