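# qPCR relative quantification by the comparative Ct (2^-ddCt) method,
# normalized to a reference small RNA (U6 by default), with stage
# comparisons by Student's t-test on delta-Ct values.

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate: dCt = Ct_miRNA - Ct_reference (paired by replicate
#' index within stage); ddCt = dCt - mean(dCt at the reference stage);
#' relative expression = 2^-ddCt. The summary also reports the
#' mean-based fold change 2^-(mean dCt_stage - mean dCt_ref), which is
#' exactly 1 at the reference stage.
#'
#' @param ct data.frame with columns `mirna`, `stage`, `replicate`, `ct`,
#'   including rows for the reference assay at every stage/replicate.
#' @param reference_stage stage used as the ddCt baseline.
#' @param reference_assay name of the normalizer rows (default `"U6"`).
#' @return list of class `ddct_result`: `detail` (per replicate: dct,
#'   ddct, rel_expr), `summary` (per mirna/stage: mean_dct, ddct,
#'   fold_change, mean_rel, sd_rel, n), `stages`, `reference_stage`.
#' @export
ddct <- function(ct, reference_stage, reference_assay = "U6") {
  stopifnot(is.data.frame(ct),
            all(c("mirna", "stage", "replicate", "ct") %in% names(ct)))
  ct$stage <- as.character(ct$stage)
  if (!reference_assay %in% ct$mirna) {
    stop("reference assay '", reference_assay, "' missing from Ct table")
  }
  if (!reference_stage %in% ct$stage) {
    stop("reference stage '", reference_stage, "' missing from Ct table")
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("Ct values must be finite and positive")
  }
  ref <- ct[ct$mirna == reference_assay, ]
  key <- function(stage, rep) paste(stage, rep, sep = "\r")
  ref_ct <- setNames(ref$ct, key(ref$stage, ref$replicate))
  tgt <- ct[ct$mirna != reference_assay, ]
  k <- key(tgt$stage, tgt$replicate)
  if (any(!k %in% names(ref_ct))) {
    miss <- tgt[!k %in% names(ref_ct), ][1, ]
    stop(sprintf("missing %s Ct for stage %s replicate %s",
                 reference_assay, miss$stage, miss$replicate))
  }
  tgt$dct <- tgt$ct - ref_ct[k]
  detail <- do.call(rbind, lapply(split(tgt, tgt$mirna), function(d) {
    ref_rows <- d$stage == reference_stage
    if (!any(ref_rows)) {
      stop("miRNA ", d$mirna[1], " has no rows at the reference stage")
    }
    d$ddct <- d$dct - mean(d$dct[ref_rows])
    d$rel_expr <- 2^(-d$ddct)
    d
  }))
  rownames(detail) <- NULL
  summ <- do.call(rbind, lapply(
    split(detail, list(detail$mirna, detail$stage), drop = TRUE),
    function(d) {
      data.frame(mirna = d$mirna[1], stage = d$stage[1],
                 mean_dct = mean(d$dct), ddct = mean(d$ddct),
                 fold_change = 2^(-mean(d$ddct)),
                 mean_rel = mean(d$rel_expr), sd_rel = sd(d$rel_expr),
                 n = nrow(d), stringsAsFactors = FALSE)
    }))
  summ <- summ[order(summ$mirna, summ$stage), ]
  rownames(summ) <- NULL
  stages <- sort(unique(detail$stage))
  structure(list(detail = detail, summary = summ, stages = stages,
                 reference_stage = as.character(reference_stage)),
            class = "ddct_result")
}

# Student's t on two samples, with the degenerate-variance conventions:
# both groups constant and equal -> p = 1; constant but different -> p = 0.
student_t <- function(x, y, paired = FALSE) {
  if (paired) {
    d <- x - y
    if (sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
    return(t.test(d)$p.value)
  }
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  t.test(x, y, var.equal = TRUE)$p.value
}

#' Test stage differences in expression
#'
#' For each miRNA, a two-sided Student's t-test on the dCt replicates
#' compares the final stage against each earlier stage. A miRNA is
#' flagged significant when the largest of those p-values is below
#' `alpha` (i.e. the final stage differs from every earlier stage), and
#' its direction comes from the sign of the mean dCt change (lower dCt =
#' higher expression).
#'
#' @param res a [ddct()] result.
#' @param final_stage the stage compared against the earlier ones
#'   (default: last stage in sort order).
#' @param alpha significance level (default 0.01).
#' @param paired use a paired t-test (replicates across stages are
#'   usually independent biological samples, so the default is unpaired).
#' @param adjust p-value adjustment method across miRNAs applied to
#'   `p_max` (`"none"` by default; e.g. `"BH"`).
#' @return data.frame per miRNA: one `p_<stage>` column per earlier
#'   stage, `p_max`, `significant`, `direction` (up/down/unchanged).
#' @export
stage_test <- function(res, final_stage = NULL, alpha = 0.01,
                       paired = FALSE, adjust = "none") {
  stopifnot(inherits(res, "ddct_result"))
  stages <- res$stages
  if (is.null(final_stage)) final_stage <- stages[length(stages)]
  final_stage <- as.character(final_stage)
  earlier <- setdiff(stages, final_stage)
  if (length(earlier) == 0L) stop("need at least two stages")
  rows <- lapply(split(res$detail, res$detail$mirna), function(d) {
    xf <- d$dct[d$stage == final_stage]
    ps <- vapply(earlier, function(s) {
      xe <- d$dct[d$stage == s]
      if (length(xf) < 2L || length(xe) < 2L) {
        stop("need >= 2 replicates per stage for ", d$mirna[1])
      }
      student_t(xf, xe, paired = paired)
    }, numeric(1))
    higher <- vapply(earlier, function(s)
      mean(xf) < mean(d$dct[d$stage == s]), logical(1))
    out <- data.frame(mirna = d$mirna[1], stringsAsFactors = FALSE)
    for (s in earlier) out[[paste0("p_", s)]] <- ps[[s]]
    out$p_max <- max(ps)
    out$direction_raw <- if (all(higher)) "up" else
      if (all(!higher)) "down" else "mixed"
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- p.adjust(out$p_max, method = adjust)
  out$significant <- out$p_adj < alpha
  out$direction <- ifelse(out$significant & out$direction_raw != "mixed",
                          out$direction_raw, "unchanged")
  out$direction_raw <- NULL
  out
}

#' Row-clustered expression matrix for heatmap display
#'
#' Hierarchically clusters log2 fold-change profiles with correlation
#' distance (1 - Pearson) and average linkage. Constant rows, for which
#' Pearson correlation is undefined, are placed at distance 0 from
#' identical rows and 1 from everything else.
#'
#' @param res a [ddct()] result with at least two miRNAs.
#' @param method linkage method for [stats::hclust()].
#' @return list: `matrix` (log2 fold change, rows in dendrogram order),
#'   `hclust`, `order` (row order as input row names).
#' @export
cluster_heatmap_matrix <- function(res, method = "average") {
  stopifnot(inherits(res, "ddct_result"))
  s <- res$summary
  mirnas <- sort(unique(s$mirna))
  if (length(mirnas) < 2L) stop("need at least two miRNAs to cluster")
  mat <- matrix(NA_real_, length(mirnas), length(res$stages),
                dimnames = list(mirnas, res$stages))
  for (i in seq_len(nrow(s))) {
    mat[s$mirna[i], s$stage[i]] <- log2(s$fold_change[i])
  }
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(mirnas, mirnas))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      xi <- mat[i, ]
      xj <- mat[j, ]
      d <- if (sd(xi) == 0 || sd(xj) == 0) {
        if (isTRUE(all.equal(xi, xj))) 0 else 1
      } else 1 - cor(xi, xj)
      D[i, j] <- D[j, i] <- d
    }
  }
  hc <- hclust(as.dist(D), method = method)
  list(matrix = mat[hc$order, , drop = FALSE], hclust = hc,
       order = mirnas[hc$order])
}

#' Stage-ordered expression profile of one miRNA
#'
#' @param res a [ddct()] result.
#' @param mirna miRNA id.
#' @param stages stage order (default: the result's sorted stages).
#' @return named numeric vector of fold changes across stages, with
#'   attribute `constant` flagging zero-variance profiles.
#' @export
stage_profile_vector <- function(res, mirna, stages = res$stages) {
  stopifnot(inherits(res, "ddct_result"))
  if (length(stages) < 2L) stop("need at least two stages for a profile")
  s <- res$summary[res$summary$mirna == mirna, ]
  if (nrow(s) == 0L) stop("unknown miRNA: ", mirna)
  if (!all(stages %in% s$stage)) {
    stop("missing stages for ", mirna, ": ",
         paste(setdiff(stages, s$stage), collapse = ", "))
  }
  v <- setNames(s$fold_change[match(stages, s$stage)], stages)
  attr(v, "constant") <- sd(v) == 0
  v
}
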