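#' Transcription efficiency: mRNA per binding event
#'
#' Multiplies a gene's mRNA synthesis rate (mRNA/cell/min) by the chromatin
#' residence time of the factor (min) to give the expected number of mRNA
#' molecules produced per binding event. On the log2 scale, values below
#' zero mean multiple binding events are needed per mRNA synthesized; a
#' zero rate maps to a missing log2 value.
#'
#' @param rate Synthesis rate in mRNA/cell/min (`>= 0`, vectorised).
#' @param t_half Residence time in minutes (`> 0`, vectorised).
#' @return A tibble with columns `te` and `log2_te`.
#' @examples
#' transcription_efficiency(0.5, 2) # te = 1, log2_te = 0
#' @export
transcription_efficiency <- function(rate, t_half) {
  if (any(rate < 0, na.rm = TRUE)) stop("`rate` must be nonnegative", call. = FALSE)
  if (any(t_half <= 0, na.rm = TRUE)) stop("`t_half` must be positive", call. = FALSE)
  te <- rate * t_half
  tibble::tibble(te = te, log2_te = ifelse(te > 0, log2(te), NA_real_))
}

#' Split genes into synthesis-rate quartiles
#'
#' Rank-based assignment of genes into four near-equal groups by synthesis
#' rate (`ntile` semantics: group sizes differ by at most one, ties broken
#' by stable input order).
#'
#' @param rates A data frame with columns `gene_id` and `rate`.
#' @return The input with an added integer `quartile` column (1 = lowest
#'   rates).
#' @export
quartile_split <- function(rates) {
  stopifnot(is.data.frame(rates), all(c("gene_id", "rate") %in% names(rates)))
  if (nrow(rates) < 4) stop("need at least 4 genes for quartiles", call. = FALSE)
  dplyr::mutate(rates, quartile = dplyr::ntile(.data$rate, 4))
}

#' Summarize residence times by class and synthesis quartile
#'
#' Joins per-site residence records to per-gene synthesis rates and
#' produces the cohort summaries used to relate binding kinetics to
#' transcription: counts of sites per residence class, and for numerically
#' estimated sites the residence-time distribution within each
#' synthesis-rate quartile (median, quartiles, and 1.5 x IQR whisker
#' bounds) together with transcription efficiency. Reliably fast sites have
#' no numeric residence time and are excluded from numeric summaries;
#' records whose gene has no synthesis rate are counted in an `unmatched`
#' bucket.
#'
#' @param records Residence records: `site_id`, `gene_id`, `class`,
#'   `t_half`.
#' @param rates Synthesis-rate table: `gene_id`, `rate`.
#' @return A list of class `cc_summary` with tibbles `class_counts`,
#'   `by_quartile`, `te` (per-gene transcription efficiency for estimated
#'   sites), and `n_unmatched`.
#' @export
summarize_by_class <- function(records, rates) {
  stopifnot(is.data.frame(records), is.data.frame(rates))
  need <- c("site_id", "gene_id", "class", "t_half")
  if (!all(need %in% names(records))) {
    stop("`records` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::left_join(records, rates, by = "gene_id")
  if (!nrow(joined)) stop("empty join between records and rates", call. = FALSE)
  n_unmatched <- sum(is.na(joined$rate))

  class_counts <- joined |>
    dplyr::count(.data$class, name = "n_sites")

  est <- joined |>
    dplyr::filter(.data$class == "estimated", !is.na(.data$rate))
  if (nrow(est) >= 4) {
    est <- quartile_split(est)
    by_quartile <- est |>
      dplyr::group_by(.data$quartile) |>
      dplyr::summarise(
        n = dplyr::n(),
        median_t_half = stats::median(.data$t_half),
        q1 = stats::quantile(.data$t_half, 0.25, names = FALSE),
        q3 = stats::quantile(.data$t_half, 0.75, names = FALSE),
        whisker_lo = max(min(.data$t_half),
                         stats::quantile(.data$t_half, 0.25, names = FALSE) -
                           1.5 * stats::IQR(.data$t_half)),
        whisker_hi = min(max(.data$t_half),
                         stats::quantile(.data$t_half, 0.75, names = FALSE) +
                           1.5 * stats::IQR(.data$t_half)),
        .groups = "drop"
      )
    te <- dplyr::bind_cols(
      dplyr::select(est, "site_id", "gene_id", "rate", "t_half", "quartile"),
      transcription_efficiency(est$rate, est$t_half)
    )
  } else {
    by_quartile <- tibble::tibble(
      quartile = integer(), n = integer(), median_t_half = double(),
      q1 = double(), q3 = double(), whisker_lo = double(),
      whisker_hi = double()
    )
    te <- tibble::tibble(site_id = character(), gene_id = character(),
                         rate = double(), t_half = double(),
                         quartile = integer(), te = double(),
                         log2_te = double())
  }

  structure(
    list(class_counts = class_counts, by_quartile = by_quartile,
         te = te, n_unmatched = n_unmatched),
    class = "cc_summary"
  )
}

#' @export
print.cc_summary <- function(x, ...) {
  cat("Residence-time cohort summary\n")
  print(x$class_counts)
  if (nrow(x$by_quartile)) {
    cat("residence time by synthesis quartile:\n")
    print(x$by_quartile)
  }
  if (x$n_unmatched) cat(x$n_unmatched, "records without a synthesis rate\n")
  invisible(x)
}

#' Plot residence times by synthesis-rate quartile
#'
#' Boxplots of estimated residence times within each mRNA synthesis-rate
#' quartile (whiskers at 1.5 x IQR).
#'
#' @param summary A `cc_summary` from [summarize_by_class()].
#' @return A ggplot object.
#' @export
plot_quartile_boxes <- function(summary) {
  stopifnot(inherits(summary, "cc_summary"), nrow(summary$te) > 0)
  ggplot2::ggplot(summary$te,
                  ggplot2::aes(x = factor(.data$quartile), y = .data$t_half)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = "synthesis-rate quartile", y = "residence time (min)",
                  title = "Residence time by synthesis quartile")
}

#' Plot the transcription-efficiency distribution
#'
#' Violin of per-gene log2 transcription efficiency; values below zero mean
#' more than one binding event per synthesized mRNA.
#'
#' @param summary A `cc_summary` from [summarize_by_class()].
#' @return A ggplot object.
#' @export
plot_te_distribution <- function(summary) {
  stopifnot(inherits(summary, "cc_summary"), nrow(summary$te) > 0)
  d <- dplyr::filter(summary$te, !is.na(.data$log2_te))
  ggplot2::ggplot(d, ggplot2::aes(x = "all sites", y = .data$log2_te)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "log2 TE (mRNA per binding event)",
                  title = "Transcription efficiency")
}
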