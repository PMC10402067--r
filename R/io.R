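#' Read a per-site count matrix from TSV
#'
#' Expects a `site_id` column plus one column per time point named `t_<min>`
#' (e.g. `t_0`, `t_10`, ...).
#'
#' @param path Path to a tab-separated file.
#' @return A count-matrix tibble.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("count matrix file not found: ", path, call. = FALSE)
  }
  out <- readr::read_tsv(path, show_col_types = FALSE)
  count_cols(out)  # validates shape
  out
}

#' Write a per-site count matrix to TSV
#'
#' @param counts A count-matrix tibble (`site_id` + `t_*` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  count_cols(counts)
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read peak regions from a BED file
#'
#' Reads the first three BED columns (0-based half-open intervals) plus an
#' optional fourth name column used as `site_id`; absent names are filled
#' with `site_<row>`.
#'
#' @param path Path to a BED file.
#' @return A tibble: `chrom`, `start`, `end`, `site_id`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  if (ncol(raw) < 3) stop("BED file needs at least 3 columns: ", path,
                          call. = FALSE)
  out <- tibble::tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    site_id = if (ncol(raw) >= 4) as.character(raw[[4]]) else
      sprintf("site_%d", seq_len(nrow(raw)))
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$end <= out$start)
  if (length(bad)) stop("malformed BED interval at line ", bad[1], call. = FALSE)
  out
}

#' Write peak regions to a BED file
#'
#' @param regions Tibble with `chrom`, `start`, `end`, `site_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(regions[c("chrom", "start", "end", "site_id")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Write a fitted induction model to a plain-text file
#'
#' Key-value format readable by [read_induction_model()] and by eye.
#'
#' @param model A `cc_induction_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_induction_model <- function(model, path) {
  stopifnot(inherits(model, "cc_induction_fit"))
  writeLines(c(
    sprintf("XP\t%.*g", 15, model$XP),
    sprintf("t_half_ind\t%.*g", 15, model$t_half_ind),
    sprintf("n\t%d", model$n),
    sprintf("adj_r2\t%.*g", 15, model$adj_r2)
  ), path)
  invisible(path)
}

#' Read a fitted induction model written by [write_induction_model()]
#'
#' @param path Path to the key-value file.
#' @return A `cc_induction_fit`.
#' @export
read_induction_model <- function(path) {
  if (!file.exists(path)) stop("induction model file not found: ", path,
                               call. = FALSE)
  kv <- readr::read_tsv(path, col_names = c("key", "value"),
                        show_col_types = FALSE)
  get1 <- function(k) as.numeric(kv$value[kv$key == k][1])
  m <- induction_model(XP = get1("XP"), t_half_ind = get1("t_half_ind"),
                       n = get1("n"))
  m$adj_r2 <- get1("adj_r2")
  m
}
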