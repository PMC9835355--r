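#' TMM normalization factors
#'
#' Trimmed mean of M-values: each sample is compared with a reference
#' column (the sample whose library size is closest to the mean library
#' size) on features expressed in both; log ratios (M) are trimmed by 30%
#' on each side and log abundances (A) by 5% on each side, and the
#' remaining M values are averaged with inverse-variance (delta-method)
#' weights. Factors are rescaled to geometric mean 1.
#'
#' @param table a [count_table] or nonnegative integer matrix.
#' @return Named numeric vector of normalization factors, one per sample.
#' @export
tmm_factors <- function(table) {
  mat <- if (inherits(table, "count_table")) table$matrix else as.matrix(table)
  if (ncol(mat) < 2L) stop("need >= 2 samples", call. = FALSE)
  lib <- colSums(mat)
  if (any(lib == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(mat)[lib == 0], collapse = ", "), call. = FALSE)
  }
  ref <- which.min(abs(lib - mean(lib)))
  f <- vapply(seq_len(ncol(mat)), function(j) {
    tmm_pair(mat[, j], lib[j], mat[, ref], lib[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(mat))
}

# single-pair TMM (edgeR-default trims: logratioTrim 0.3, sumTrim 0.05)
tmm_pair <- function(obs, lib_obs, ref, lib_ref) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  p_obs <- obs[keep] / lib_obs
  p_ref <- ref[keep] / lib_ref
  m <- log2(p_obs / p_ref)
  a <- 0.5 * log2(p_obs * p_ref)
  w <- (lib_obs - obs[keep]) / (lib_obs * obs[keep]) +
    (lib_ref - ref[keep]) / (lib_ref * ref[keep])
  if (max(abs(m)) < 1e-10) return(1)
  n <- length(m)
  lo_m <- floor(n * 0.3) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * 0.05) + 1
  hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Two-group negative-binomial exact test
#'
#' Per-feature differential abundance between two treatments. Counts are
#' scaled to a common effective library size (TMM-normalized) yielding
#' integer pseudo-counts; a common dispersion is estimated by a pooled
#' method-of-moments estimator (unless supplied); the p-value is the
#' conditional NB exact test probability: conditioning on the feature's
#' total pseudo-count, the probability of group splits at most as likely
#' as the observed one. Benjamini-Hochberg q-values control the FDR;
#' features with q below `alpha` are called significant.
#'
#' @param table a [count_table] containing both groups.
#' @param group_a,group_b treatment labels from the design; positive
#'   `log2_fold_change` means enriched in `group_a`.
#' @param dispersion `"auto"` (pooled method-of-moments common
#'   dispersion) or a fixed nonnegative value.
#' @param alpha FDR threshold for the `significant` call (default 0.05).
#' @return data.frame with one row per feature: `feature`,
#'   `log2_fold_change`, `p_value`, `q_value`, `direction`
#'   (`"treatment-enriched"` when enriched in `group_a`,
#'   `"control-enriched"` otherwise) and `significant`.
#' @export
exact_nb_test <- function(table, group_a, group_b, dispersion = "auto",
                          alpha = 0.05) {
  stopifnot(inherits(table, "count_table"))
  design <- table$design
  sa <- design$sample[design$treatment == group_a]
  sb <- design$sample[design$treatment == group_b]
  if (length(sa) < 2L || length(sb) < 2L) {
    stop("each group needs >= 2 replicates (", group_a, ": ", length(sa),
         ", ", group_b, ": ", length(sb), ")", call. = FALSE)
  }
  mat <- table$matrix[, c(sa, sb), drop = FALSE]
  f <- tmm_factors(mat)
  eff <- colSums(mat) * f
  target <- exp(mean(log(eff)))
  pseudo <- round(sweep(mat, 2, target / eff, `*`))
  storage.mode(pseudo) <- "integer"

  na <- length(sa)
  nb <- length(sb)
  ga <- pseudo[, sa, drop = FALSE]
  gb <- pseudo[, sb, drop = FALSE]

  if (identical(dispersion, "auto")) {
    phi <- pooled_mom_dispersion(ga, gb)
  } else {
    phi <- as.numeric(dispersion)
    stopifnot(is.finite(phi), phi >= 0)
  }
  phi <- max(phi, 1e-6)

  suma <- rowSums(ga)
  sumb <- rowSums(gb)
  p <- vapply(seq_len(nrow(pseudo)), function(i) {
    nb_exact_p(suma[i], sumb[i], na, nb, phi)
  }, numeric(1))

  ma <- suma / na
  mb <- sumb / nb
  zero <- ma == 0 | mb == 0
  lfc <- ifelse(zero, log2((ma + 0.5) / (mb + 0.5)), log2(ma / mb))

  q <- p.adjust(p, method = "BH")
  data.frame(
    feature = rownames(pseudo),
    log2_fold_change = lfc,
    p_value = p,
    q_value = q,
    direction = ifelse(lfc >= 0, "treatment-enriched", "control-enriched"),
    significant = q <= alpha,
    stringsAsFactors = FALSE,
    row.names = NULL)
}

# pooled method-of-moments common dispersion on pseudo-counts:
# E[s^2 - mean] = phi * mean^2 within each group, summed over features
pooled_mom_dispersion <- function(ga, gb) {
  num <- 0
  den <- 0
  for (g in list(ga, gb)) {
    m <- rowMeans(g)
    v <- apply(g, 1, var)
    keep <- m > 0
    num <- num + sum(v[keep] - m[keep])
    den <- den + sum(m[keep]^2)
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

# conditional two-sided exact test: P(splits with probability <= observed)
nb_exact_p <- function(sa, sb, na, nb, phi) {
  t <- sa + sb
  if (t == 0) return(1)
  mu <- t / (na + nb)
  y <- 0:t
  lp <- dnbinom(y, size = na / phi, mu = na * mu, log = TRUE) +
    dnbinom(t - y, size = nb / phi, mu = nb * mu, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp)
  obs <- pr[sa + 1]
  sum(pr[pr <= obs * (1 + 1e-10)]) / sum(pr)
}

#' Read a precomputed differential-abundance table
#'
#' Injection port for externally computed results (e.g. an edgeR
#' `exactTest` top table): a TSV with columns `feature`, `logFC` (or
#' `log2_fold_change`), `p` (or `PValue`/`p_value`) and optionally `q`
#' (`FDR`/`q_value`; recomputed by BH when absent).
#'
#' @param path TSV file.
#' @param alpha FDR threshold for the `significant` call.
#' @return data.frame in the same shape as [exact_nb_test()].
#' @export
read_precomputed_da <- function(path, alpha = 0.05) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  pick <- function(candidates) {
    hit <- intersect(candidates, names(tb))
    if (length(hit) == 0L) {
      stop("precomputed DA table needs one of: ",
           paste(candidates, collapse = ", "), call. = FALSE)
    }
    tb[[hit[1]]]
  }
  feature <- as.character(pick(c("feature", "id")))
  lfc <- as.numeric(pick(c("logFC", "log2_fold_change", "log2FC")))
  p <- as.numeric(pick(c("p", "PValue", "p_value")))
  q <- tryCatch(as.numeric(pick(c("q", "FDR", "q_value"))),
                error = function(e) p.adjust(p, "BH"))
  data.frame(feature = feature, log2_fold_change = lfc, p_value = p,
             q_value = q,
             direction = ifelse(lfc >= 0, "treatment-enriched",
                                "control-enriched"),
             significant = q <= alpha,
             stringsAsFactors = FALSE)
}

#' Significant features of a DA result, optionally by direction
#' @param da data.frame from [exact_nb_test()] or [read_precomputed_da()].
#' @param direction `"treatment-enriched"`, `"control-enriched"` or
#'   `NULL` for both.
#' @return Character vector of feature ids.
#' @export
da_significant <- function(da, direction = NULL) {
  keep <- da$significant
  if (!is.null(direction)) keep <- keep & da$direction == direction
  da$feature[keep]
}
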