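#' Split patients by membership of a gene in their personalized subgraph
#'
#' @param collection Named list mapping patient id to that patient's
#'   personalized subgraph node set (character vector).
#' @param gene Single gene/node id.
#' @return List with sorted character vectors `with` and `without`; the
#'   two always partition the patients.
#' @export
stratify_by_gene <- function(collection, gene) {
  stopifnot(is.list(collection), !is.null(names(collection)),
            length(gene) == 1L)
  has <- vapply(collection, function(s) gene %in% s, logical(1))
  list(with = sort(names(collection)[has]),
       without = sort(names(collection)[!has]))
}

check_survival <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("patient_id", "time", "event") %in% names(records)))
  if (any(records$time < 0)) stop("follow-up times must be >= 0", call. = FALSE)
  records$patient_id <- as.character(records$patient_id)
  records$event <- as.integer(as.logical(records$event))
  records
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function; returns a
#' right-continuous non-increasing step function with S(0) = 1. The
#' underlying `survival::survfit` object is attached as the `"fit"`
#' attribute.
#'
#' @param records Data frame with columns `patient_id`, `time`
#'   (non-negative), `event` (1/TRUE = death observed, 0/FALSE =
#'   censored).
#' @return A function `S(t)`.
#' @export
km_estimate <- function(records) {
  records <- check_survival(records)
  if (nrow(records) == 0L) stop("no survival records", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  times <- summary(fit, censored = FALSE)$time
  surv <- summary(fit, censored = FALSE)$surv
  f <- if (length(times) == 0L) {
    function(t) rep(1, length(t))  # no events: S is identically 1
  } else {
    stats::stepfun(times, c(1, surv), right = FALSE)
  }
  attr(f, "fit") <- fit
  f
}

#' Two-group log-rank test
#'
#' Standard unweighted log-rank statistic on one degree of freedom with
#' the usual aggregated treatment of tied event times; the p-value is the
#' chi-square upper tail. When neither group has any event the test is
#' degenerate and `chi_square = 0`, `p_value = 1` is returned with a
#' warning.
#'
#' @param group_a,group_b Survival record data frames (see
#'   [km_estimate()]); both must be non-empty.
#' @return One-row tibble with `chi_square`, `p_value`, `n_a`, `n_b`,
#'   `degenerate`.
#' @export
logrank_test <- function(group_a, group_b) {
  group_a <- check_survival(group_a)
  group_b <- check_survival(group_b)
  if (nrow(group_a) == 0L || nrow(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  dat <- rbind(cbind(group_a, group = "a"), cbind(group_b, group = "b"))
  degenerate <- sum(dat$event) == 0L
  if (degenerate) {
    warning("no events in either group; log-rank test is degenerate",
            call. = FALSE)
    chi <- 0
    p <- 1
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
    chi <- unname(sd$chisq)
    p <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)
  }
  tibble::tibble(chi_square = chi, p_value = p, n_a = nrow(group_a),
                 n_b = nrow(group_b), degenerate = degenerate)
}

#' Network-defined genes: survival stratification by subgraph membership
#'
#' For every gene appearing in at least one patient's personalized
#' subgraph, patients are split by whether their subgraph contains the
#' gene; genes yielding two strata of at least `min_group_size` patients
#' are tested with the log-rank test. Raw p-values are reported alongside
#' the multiplicity-adjusted ones and the table is ranked by ascending
#' (adjusted) p-value; genes passing `alpha` are flagged.
#'
#' @param collection Named list: patient id to subgraph node set.
#' @param survival_records Data frame with `patient_id`, `time`, `event`;
#'   every patient in `collection` must have a record.
#' @param min_group_size Minimum stratum size for a gene to be tested.
#' @param alpha Significance level applied to the ranking p-value.
#' @param correction `"benjamini-hochberg"` (default) or `"none"`.
#' @return Tibble with columns `gene`, `n_with`, `n_without`,
#'   `chi_square`, `p`, `p_adjusted`, `significant`; empty (not an error)
#'   when no gene qualifies.
#' @export
network_defined_genes <- function(collection, survival_records,
                                  min_group_size = 3L, alpha = 0.05,
                                  correction = c("benjamini-hochberg",
                                                 "none")) {
  correction <- match.arg(correction)
  survival_records <- check_survival(survival_records)
  patients <- names(collection)
  missing <- setdiff(patients, survival_records$patient_id)
  if (length(missing) > 0L) {
    stop("patients without survival records: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  empty <- tibble::tibble(gene = character(), n_with = integer(),
                          n_without = integer(), chi_square = double(),
                          p = double(), p_adjusted = double(),
                          significant = logical())
  genes <- sort(unique(unlist(collection)))
  if (length(genes) == 0L) return(empty)
  rows <- purrr::map(genes, function(gene) {
    strata <- stratify_by_gene(collection, gene)
    if (length(strata$with) < min_group_size ||
        length(strata$without) < min_group_size) {
      return(NULL)
    }
    a <- survival_records[survival_records$patient_id %in% strata$with, ]
    b <- survival_records[survival_records$patient_id %in% strata$without, ]
    lr <- suppressWarnings(logrank_test(a, b))
    tibble::tibble(gene = gene, n_with = length(strata$with),
                   n_without = length(strata$without),
                   chi_square = lr$chi_square, p = lr$p_value)
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0L) return(empty)
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- if (correction == "benjamini-hochberg") {
    stats::p.adjust(out$p, method = "BH")
  } else {
    out$p
  }
  out$significant <- out$p_adjusted <= alpha
  dplyr::arrange(out, .data$p_adjusted, .data$p, .data$gene)
}

#' Kaplan-Meier curves for a two-way patient stratification
#'
#' @param survival_records Survival record data frame.
#' @param with,without Character vectors of patient ids (e.g. from
#'   [stratify_by_gene()]).
#' @param label Name of the stratifying gene, used in the legend.
#' @return A ggplot object with one survival step line per stratum.
#' @export
plot_km_strata <- function(survival_records, with, without, label = "gene") {
  survival_records <- check_survival(survival_records)
  grab <- function(ids, grp) {
    rec <- survival_records[survival_records$patient_id %in% ids, ]
    if (nrow(rec) == 0L) return(NULL)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
    tibble::tibble(time = c(0, fit$time), survival = c(1, fit$surv),
                   group = grp)
  }
  dat <- dplyr::bind_rows(grab(with, paste0("with ", label)),
                          grab(without, paste0("without ", label)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$survival,
                                    color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", color = NULL) +
    ggplot2::theme_bw()
}
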