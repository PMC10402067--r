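#' Depth-normalize a count matrix
#'
#' Scales each time-point column of a per-site read-count matrix so all
#' column sums equal the mean original depth. Relative values within a
#' column are unchanged; columns that already share a common depth pass
#' through untouched.
#'
#' @param counts A count matrix as a tibble: `site_id` plus one numeric
#'   column per time point.
#' @return A tibble of the same shape with equalized column depths.
#' @export
depth_normalize <- function(counts) {
  m <- count_cols(counts)
  depths <- colSums(counts[m])
  if (any(depths == 0)) {
    stop("zero total depth in column(s): ",
         paste(m[depths == 0], collapse = ", "), call. = FALSE)
  }
  target <- mean(depths)
  counts[m] <- purrr::map2(counts[m], depths, function(col, d) col * target / d)
  counts
}

#' Scale HA counts to measured protein levels
#'
#' The HA (competitor) channel is sequenced to an arbitrary depth at each
#' time point, so after depth normalization its absolute scale relative to
#' the Myc channel is unknown. This step anchors it to protein data: each HA
#' column is multiplied so that the genome-wide mean HA/Myc count ratio at
#' that time equals the HA/Myc relative protein level measured by Western
#' blotting (or predicted by a fitted induction model).
#'
#' @param ha,myc Depth-normalized count matrices (`site_id` + time columns).
#' @param protein Either a `cc_induction_fit` (the protein ratio is the
#'   fitted Hill curve) or a data frame with columns `time` and `ratio`
#'   covering every time point of the matrices.
#' @return The rescaled HA count matrix.
#' @export
scale_ha_to_protein <- function(ha, myc, protein) {
  m <- count_cols(ha)
  if (!identical(m, count_cols(myc))) {
    stop("HA and Myc matrices must share time-point columns", call. = FALSE)
  }
  times <- col_times(m)
  p <- if (inherits(protein, "cc_induction_fit")) {
    induction_curve(protein, times)
  } else {
    stopifnot(is.data.frame(protein), all(c("time", "ratio") %in% names(protein)))
    idx <- match(times, protein$time)
    if (anyNA(idx)) {
      stop("no protein-level value for time point(s): ",
           paste(times[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    protein$ratio[idx]
  }
  for (j in seq_along(m)) {
    mean_ratio <- mean(ha[[m[j]]] / myc[[m[j]]])
    if (mean_ratio <= 0 && p[j] > 0) {
      stop("cannot anchor HA column with zero mean ratio: ", m[j], call. = FALSE)
    }
    ha[[m[j]]] <- if (p[j] == 0) 0 * ha[[m[j]]] else
      ha[[m[j]]] * p[j] / mean_ratio
  }
  ha
}

#' Compute the per-site HA/Myc ratio table
#'
#' Elementwise division of the normalized HA matrix by the normalized Myc
#' matrix, `(HA + pseudocount) / (Myc + pseudocount)`, returned as a long
#' ratio table ready for turnover fitting. With the default pseudocount of 0
#' a zero Myc entry is an error; a small pseudocount keeps sparse
#' simulations finite.
#'
#' @param ha,myc Normalized count matrices with matching sites and times.
#' @param pseudocount Added to both channels before division. Default 0.
#' @return A long tibble: `site_id`, `time`, `R`.
#' @export
compute_ratio_table <- function(ha, myc, pseudocount = 0) {
  m <- count_cols(ha)
  if (!identical(m, count_cols(myc)) ||
      !identical(ha$site_id, myc$site_id)) {
    stop("HA and Myc matrices must share sites and time-point columns",
         call. = FALSE)
  }
  denom_zero <- purrr::map_lgl(myc[m], function(col) any(col + pseudocount == 0))
  if (any(denom_zero)) {
    stop("zero Myc counts with zero pseudocount in column(s): ",
         paste(m[denom_zero], collapse = ", "), call. = FALSE)
  }
  out <- ha
  out[m] <- purrr::map2(ha[m], myc[m],
                        function(h, y) (h + pseudocount) / (y + pseudocount))
  tidyr::pivot_longer(out, dplyr::all_of(m),
                      names_to = "time", values_to = "R") |>
    dplyr::mutate(time = as.numeric(sub("^t_", "", .data$time))) |>
    dplyr::arrange(.data$site_id, .data$time)
}

#' Assign peak regions to genes within the promoter window
#'
#' Each region is assigned to the gene with the nearest TSS by strand-aware
#' signed distance from the region midpoint (negative = upstream of the
#' TSS). Assignments are kept only when the distance falls within the
#' promoter window (default -250 to +100 bp, inclusive); when several
#' regions map to one gene only the closest survives; and regions assigned
#' to tRNA genes are removed. Equidistant TSSs are broken towards the
#' lexicographically smallest `gene_id` so builds are deterministic.
#'
#' @param regions BED-style tibble: `chrom`, `start`, `end` (0-based
#'   half-open) and a `site_id` column.
#' @param annotation TSS table: `gene_id`, `chrom`, `tss` (1-based),
#'   `strand` (`"+"`/`"-"`), `biotype`.
#' @param window Promoter window as `c(upstream, downstream)` signed
#'   distances. Default `c(-250, 100)`.
#' @param drop_biotypes Biotypes removed after assignment. Default `"tRNA"`.
#' @return A tibble: `site_id`, `gene_id`, `distance` (bp, signed).
#' @export
assign_regions_to_genes <- function(regions, annotation,
                                    window = c(-250, 100),
                                    drop_biotypes = "tRNA") {
  stopifnot(is.data.frame(regions), is.data.frame(annotation),
            nrow(annotation) > 0)
  need_r <- c("chrom", "start", "end", "site_id")
  need_a <- c("gene_id", "chrom", "tss", "strand", "biotype")
  if (!all(need_r %in% names(regions))) {
    stop("`regions` needs columns ", paste(need_r, collapse = ", "), call. = FALSE)
  }
  if (!all(need_a %in% names(annotation))) {
    stop("`annotation` needs columns ", paste(need_a, collapse = ", "), call. = FALSE)
  }
  if (!all(annotation$strand %in% c("+", "-"))) {
    stop("annotation strand must be '+' or '-'", call. = FALSE)
  }
  bad <- which(regions$end <= regions$start | regions$start < 0)
  if (length(bad)) {
    stop("malformed BED interval at line ", bad[1], call. = FALSE)
  }

  # midpoint in 0-based continuous coordinates; TSS converted to 0-based
  mids <- regions |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2)
  ann <- dplyr::mutate(annotation, tss0 = .data$tss - 1)

  assigned <- mids |>
    dplyr::inner_join(ann, by = "chrom", relationship = "many-to-many") |>
    dplyr::mutate(
      distance = ifelse(.data$strand == "+",
                        .data$mid - .data$tss0,
                        .data$tss0 - .data$mid)
    ) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::arrange(abs(.data$distance), .data$gene_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$distance >= window[1], .data$distance <= window[2]) |>
    dplyr::filter(!.data$biotype %in% drop_biotypes)

  # one region per gene: keep the closest
  assigned |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(abs(.data$distance), .data$site_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("site_id", "gene_id", "distance") |>
    dplyr::arrange(.data$site_id)
}

# names of the per-time-point columns of a count matrix tibble
count_cols <- function(counts) {
  stopifnot(is.data.frame(counts), "site_id" %in% names(counts))
  m <- grep("^t_", names(counts), value = TRUE)
  if (!length(m)) stop("no time-point columns (t_*) found", call. = FALSE)
  m
}

col_times <- function(cols) as.numeric(sub("^t_", "", cols))
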