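#' Trinary global expression score
#'
#' Maps a differential-expression table (per-gene log2 fold change and
#' p-value) to scores in \{-1, 0, +1\}: +1 for significant strong
#' up-regulation (`log2_fold_change > fc_cut` and `p_value < p_cut`), -1
#' for significant strong down-regulation (`log2_fold_change < -fc_cut`
#' and `p_value < p_cut`), 0 otherwise. Inequalities are strict.
#'
#' @param table Data frame with columns `gene` (or `node`),
#'   `log2_fold_change` and `p_value`.
#' @param fc_cut Absolute log2-fold-change threshold (default 2).
#' @param p_cut Significance threshold (default 0.05).
#' @return Tibble with columns `node` and `score`.
#' @export
trinary_global_score <- function(table, fc_cut = 2.0, p_cut = 0.05) {
  table <- tibble::as_tibble(table)
  if ("gene" %in% names(table) && !"node" %in% names(table)) {
    table <- dplyr::rename(table, node = "gene")
  }
  stopifnot(all(c("node", "log2_fold_change", "p_value") %in% names(table)))
  if (any(table$p_value < 0 | table$p_value > 1, na.rm = TRUE)) {
    stop("p_value must lie in [0, 1]", call. = FALSE)
  }
  dplyr::transmute(
    table,
    node = as.character(.data$node),
    score = dplyr::case_when(
      .data$log2_fold_change > fc_cut & .data$p_value < p_cut ~ 1,
      .data$log2_fold_change < -fc_cut & .data$p_value < p_cut ~ -1,
      TRUE ~ 0
    )
  )
}

#' Personalized log2 fold change against the control mean
#'
#' For one tumor sample, each gene's score is
#' `log2((tumor + pseudocount) / (mean(controls) + pseudocount))`. The
#' pseudocount is added to numerator and denominator.
#'
#' @param expr Numeric matrix (genes x samples, non-negative normalized
#'   values) with gene row names and sample column names.
#' @param sample_group Named character vector mapping sample id to
#'   `"tumor"` or `"control"`.
#' @param tumor_sample The tumor sample id to score.
#' @param pseudocount Added to both numerator and denominator (default 1).
#' @return Tibble with columns `node` and `score`.
#' @export
personalized_log2fc <- function(expr, sample_group, tumor_sample,
                                pseudocount = 1) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            !is.null(colnames(expr)))
  if (!tumor_sample %in% colnames(expr)) {
    stop("tumor sample not present in the expression matrix", call. = FALSE)
  }
  controls <- names(sample_group)[sample_group == "control"]
  controls <- intersect(controls, colnames(expr))
  if (length(controls) == 0L) {
    stop("at least one control sample is required", call. = FALSE)
  }
  ctrl_mean <- rowMeans(expr[, controls, drop = FALSE])
  tibble::tibble(
    node = rownames(expr),
    score = log2((expr[, tumor_sample] + pseudocount) /
                   (ctrl_mean + pseudocount))
  )
}

#' Trinary personalized expression score
#'
#' Thresholds personalized log2 fold changes: +1 above `cut`, -1 below
#' `-cut`, 0 otherwise (strict inequalities).
#'
#' @param fold Tibble with columns `node` and `score` (personalized log2
#'   fold changes), e.g. from [personalized_log2fc()].
#' @param cut Threshold (default 2).
#' @return Tibble with columns `node` and `score` in \{-1, 0, +1\}.
#' @export
trinary_personalized_score <- function(fold, cut = 2) {
  stopifnot(all(c("node", "score") %in% names(fold)))
  dplyr::transmute(
    tibble::as_tibble(fold),
    node = as.character(.data$node),
    score = dplyr::case_when(.data$score > cut ~ 1,
                             .data$score < -cut ~ -1,
                             TRUE ~ 0)
  )
}

#' Call differentially methylated probes from beta values
#'
#' A probe is an up-regulated DMP (+1) when the median tumor beta minus the
#' median control beta exceeds `delta`, down-regulated (-1) below
#' `-delta`, and 0 otherwise (strict inequalities).
#'
#' @param beta Numeric matrix (probes x samples) of beta values in
#'   \[0, 1\], with probe row names and sample column names.
#' @param sample_group Named character vector mapping sample id to
#'   `"tumor"` or `"control"`.
#' @param delta Median-difference threshold (default 0.2).
#' @return Tibble with columns `probe` and `call` in \{-1, 0, +1\}.
#' @export
call_dmps <- function(beta, sample_group, delta = 0.2) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  tumor <- intersect(names(sample_group)[sample_group == "tumor"],
                     colnames(beta))
  control <- intersect(names(sample_group)[sample_group == "control"],
                       colnames(beta))
  if (length(tumor) == 0L || length(control) == 0L) {
    stop("each probe needs at least one tumor and one control sample",
         call. = FALSE)
  }
  diff <- apply(beta[, tumor, drop = FALSE], 1L, stats::median) -
    apply(beta[, control, drop = FALSE], 1L, stats::median)
  tibble::tibble(
    probe = rownames(beta),
    call = dplyr::case_when(diff > delta ~ 1, diff < -delta ~ -1, TRUE ~ 0)
  )
}

#' Promoter-methylation gene score from DMP calls
#'
#' A gene is scored +1 when at least one of its promoter probes is an
#' up-regulated DMP and none is down-regulated, -1 in the mirrored case,
#' and 0 otherwise -- including conflicting calls and genes with no mapped
#' probe.
#'
#' @param dmp_calls Tibble with columns `probe` and `call` (from
#'   [call_dmps()]).
#' @param probe_gene_map Data frame with columns `probe` and `gene`
#'   (probes within 1500 bp upstream of the gene's transcription start
#'   site; supplied as input, not computed).
#' @param genes Optional character vector of genes to score (defaults to
#'   all genes in the map).
#' @return Tibble with columns `node` and `score` in \{-1, 0, +1\}.
#' @export
gene_methylation_score <- function(dmp_calls, probe_gene_map, genes = NULL) {
  stopifnot(all(c("probe", "call") %in% names(dmp_calls)),
            all(c("probe", "gene") %in% names(probe_gene_map)))
  merged <- dplyr::inner_join(tibble::as_tibble(probe_gene_map),
                              tibble::as_tibble(dmp_calls), by = "probe")
  per_gene <- merged |>
    dplyr::group_by(node = as.character(.data$gene)) |>
    dplyr::summarise(up = any(.data$call == 1), down = any(.data$call == -1),
                     .groups = "drop") |>
    dplyr::mutate(score = dplyr::case_when(.data$up & !.data$down ~ 1,
                                           .data$down & !.data$up ~ -1,
                                           TRUE ~ 0)) |>
    dplyr::select("node", "score")
  if (is.null(genes)) return(per_gene)
  dplyr::left_join(tibble::tibble(node = as.character(genes)), per_gene,
                   by = "node") |>
    dplyr::mutate(score = dplyr::coalesce(.data$score, 0))
}

#' Methylation-transcription consistency score
#'
#' Indicator that promoter methylation and transcription move in opposite
#' directions: 1 when the trinary expression score and the methylation
#' gene score have a strictly negative product, 0 otherwise.
#'
#' @param trinary Tibble with columns `node`, `score` in \{-1, 0, +1\}
#'   (expression).
#' @param methyl Tibble with columns `node`, `score` in \{-1, 0, +1\}
#'   (methylation). Genes missing from either table count as 0.
#' @return Tibble with columns `node` and `score` in \{0, 1\}.
#' @export
consistency_score <- function(trinary, methyl) {
  check_trinary <- function(x, what) {
    stopifnot(all(c("node", "score") %in% names(x)))
    if (!all(x$score %in% c(-1, 0, 1))) {
      stop(what, " scores must be valued in {-1, 0, +1}", call. = FALSE)
    }
    x
  }
  trinary <- check_trinary(trinary, "expression")
  methyl <- check_trinary(methyl, "methylation")
  dplyr::full_join(
    dplyr::select(tibble::as_tibble(trinary), "node", expr = "score"),
    dplyr::select(tibble::as_tibble(methyl), "node", meth = "score"),
    by = "node"
  ) |>
    dplyr::mutate(
      expr = dplyr::coalesce(.data$expr, 0),
      meth = dplyr::coalesce(.data$meth, 0),
      score = as.numeric(.data$expr * .data$meth < 0)
    ) |>
    dplyr::select("node", "score") |>
    dplyr::arrange(.data$node)
}

#' Element-wise absolute value of a score table
#'
#' @param scores Tibble with columns `node` and `score`.
#' @return Tibble with `score` replaced by its absolute value.
#' @export
absolute_score <- function(scores) {
  stopifnot(all(c("node", "score") %in% names(scores)))
  dplyr::mutate(tibble::as_tibble(scores), score = abs(.data$score))
}
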