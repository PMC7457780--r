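# Modified quantitative complementation test (QCT): ND-ratio distributions
# of candidate-gene mutant alleles crossed into the nocturnal (N*), diurnal
# (D*) and control (C*) backgrounds.

QCT_BACKGROUNDS <- c("D*", "C*", "N*")

normalise_background <- function(x) {
  y <- toupper(gsub("\\*", "", as.character(x)))
  if (!all(y %in% c("N", "D", "C"))) {
    abort("background labels must be among N*, D*, C* (or N, D, C)")
  }
  paste0(y, "*")
}

#' Quantitative complementation test on ND ratios
#'
#' Compares the ND-ratio distributions of a candidate gene's mutant-allele
#' crosses into the three selection backgrounds. The omnibus test is a
#' Kruskal-Wallis rank-sum test across the three crosses (2 df); all
#' pairwise contrasts are two-sample Kolmogorov-Smirnov tests (exact
#' p-values for cells of at most 25 flies, asymptotic otherwise), reported
#' raw and Benjamini-Hochberg adjusted.
#'
#' Verdict rule: `complemented` requires the background ordering
#' mean ND `D* < C* < N*`, a significant `N*` vs `D*` KS contrast, and a
#' significant Kruskal-Wallis test. Significant heterogeneity without that
#' ordering is `failed_to_complement`; anything else is `inconclusive`.
#'
#' @param data A tibble with columns `background` (`N*`/`D*`/`C*`), `nd`
#'   (ND ratio per fly) and optionally `allele` (`"mutant"`/`"control"`;
#'   only mutant rows are tested) and `gene`.
#' @param alpha Significance level.
#' @param min_n Minimum flies per cell (error below this floor).
#' @return A `qct_result` object; see [tidy.qct_result()] and
#'   [qct_matrix()].
#' @export
qct_test <- function(data, alpha = 0.05, min_n = 5) {
  data <- as_tibble(data)
  if (!all(c("background", "nd") %in% names(data))) {
    abort("data needs columns background and nd")
  }
  gene <- if ("gene" %in% names(data)) {
    g <- unique(data$gene)
    if (length(g) > 1) abort("one gene per qct_test() call")
    g
  } else NA_character_
  if ("allele" %in% names(data)) {
    data <- data %>% filter(.data$allele == "mutant")
  }
  data$background <- normalise_background(data$background)
  missing_bg <- setdiff(QCT_BACKGROUNDS, unique(data$background))
  if (length(missing_bg) > 0) {
    abort(paste0("missing mutant-allele cell(s): ",
                 paste(missing_bg, collapse = ", ")))
  }
  cells <- split(data$nd, data$background)[QCT_BACKGROUNDS]
  ns <- lengths(cells)
  if (any(ns < min_n)) {
    abort(sprintf("cell(s) below the %d-fly floor: %s", min_n,
                  paste(QCT_BACKGROUNDS[ns < min_n], collapse = ", ")))
  }
  kw <- kruskal.test(cells)
  pair_idx <- utils::combn(QCT_BACKGROUNDS, 2, simplify = FALSE)
  ties_seen <- FALSE
  ks <- purrr::map(pair_idx, function(pr) {
    x <- cells[[pr[1]]]; y <- cells[[pr[2]]]
    if (anyDuplicated(c(x, y)) > 0) ties_seen <<- TRUE
    res <- withCallingHandlers(
      ks.test(x, y, exact = max(length(x), length(y)) <= 25),
      warning = function(w) {
        if (grepl("ties", conditionMessage(w))) {
          ties_seen <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    tibble(a = pr[1], b = pr[2], D = unname(res$statistic),
           p = res$p.value)
  }) %>% bind_rows()
  if (ties_seen) {
    warn("ties present in ND values; KS p-values are approximate")
  }
  ks$p_adj <- p.adjust(ks$p, method = "BH")
  means <- purrr::map_dbl(cells, mean)
  ordering_ok <- means[["D*"]] < means[["C*"]] && means[["C*"]] < means[["N*"]]
  ks_nd <- ks %>%
    filter((.data$a == "N*" & .data$b == "D*") |
             (.data$a == "D*" & .data$b == "N*"))
  kw_sig <- kw$p.value < alpha
  ks_nd_sig <- ks_nd$p[1] < alpha
  verdict <- if (ordering_ok && ks_nd_sig && kw_sig) {
    "complemented"
  } else if ((kw_sig || ks_nd_sig) && !ordering_ok) {
    "failed_to_complement"
  } else {
    "inconclusive"
  }
  structure(
    list(gene = gene,
         kw_stat = unname(kw$statistic), kw_df = unname(kw$parameter),
         kw_p = kw$p.value,
         ks = ks,
         cell_means = tibble(background = QCT_BACKGROUNDS,
                             n = as.integer(ns), mean_nd = unname(means)),
         ordering_ok = ordering_ok, verdict = verdict, alpha = alpha),
    class = "qct_result"
  )
}

#' @export
print.qct_result <- function(x, ...) {
  cat(sprintf("<qct_result>%s KW chi2(%d) = %.2f, p = %.3g; verdict: %s\n",
              if (is.na(x$gene)) "" else paste0(" gene ", x$gene, ";"),
              x$kw_df, x$kw_stat, x$kw_p, x$verdict))
  print(x$cell_means)
  invisible(x)
}

#' Tidy the pairwise KS contrasts of a QCT result
#' @param x A `qct_result`.
#' @param ... Unused.
#' @export
tidy.qct_result <- function(x, ...) x$ks

#' @export
glance.qct_result <- function(x, ...) {
  tibble(gene = x$gene, kw_stat = x$kw_stat, kw_df = x$kw_df,
         kw_p = x$kw_p, ordering_ok = x$ordering_ok, verdict = x$verdict)
}

#' Pairwise KS matrix of a QCT result
#'
#' Lays out the pairwise Kolmogorov-Smirnov results as a 3 x 3 matrix with
#' p-values in the top half and D statistics in the bottom half.
#'
#' @param result A `qct_result`.
#' @return A numeric matrix with background row/column names.
#' @export
qct_matrix <- function(result) {
  stopifnot(inherits(result, "qct_result"))
  m <- matrix(NA_real_, 3, 3, dimnames = list(QCT_BACKGROUNDS, QCT_BACKGROUNDS))
  for (i in seq_len(nrow(result$ks))) {
    a <- result$ks$a[i]; b <- result$ks$b[i]
    lo <- QCT_BACKGROUNDS[min(match(c(a, b), QCT_BACKGROUNDS))]
    hi <- QCT_BACKGROUNDS[max(match(c(a, b), QCT_BACKGROUNDS))]
    m[lo, hi] <- result$ks$p[i]   # top half: p
    m[hi, lo] <- result$ks$D[i]   # bottom half: D
  }
  m
}
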