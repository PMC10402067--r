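#' Noise model for synthetic competition-ChIP experiments
#'
#' Bundles the three noise parameters of the generator: a multiplicative
#' lognormal coefficient of variation applied to each ratio observation, the
#' mean sequencing depth per site and time point, and a negative-binomial
#' dispersion for read counts (`0` falls back to Poisson). Ratios are
#' strictly positive, so multiplicative lognormal noise is the natural
#' choice; count overdispersion is standard for ChIP-seq.
#'
#' @param ratio_noise Lognormal CV of the per-observation ratio noise.
#' @param count_depth Mean reads per site per time point.
#' @param count_dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @return A list of class `cc_noise_model`.
#' @export
noise_model <- function(ratio_noise = 0.1, count_depth = 200,
                        count_dispersion = 0.05) {
  stopifnot(ratio_noise >= 0, count_depth >= 0, count_dispersion >= 0)
  structure(list(ratio_noise = ratio_noise, count_depth = count_depth,
                 count_dispersion = count_dispersion),
            class = "cc_noise_model")
}

# run expr with a private RNG stream; outer .Random.seed untouched
with_seed <- function(seed, expr) {
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Simulate Western-blot style induction measurements
#'
#' Draws replicated HA/Myc protein-ratio measurements from the Hill
#' induction curve with additive Gaussian noise, censored at zero (ratios
#' cannot be negative).
#'
#' @param model A `cc_induction_fit` (e.g. [induction_model()]).
#' @param timepoints Sampling times in minutes. Default [cc_timepoints()].
#' @param replicates Number of replicate series (`>= 1`). Default 3.
#' @param noise_sd Gaussian noise standard deviation on the ratio scale.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble with one row per (timepoint, replicate): `time`,
#'   `replicate`, `ratio`.
#' @examples
#' simulate_induction_measurements(induction_model(), noise_sd = 0.05, seed = 1)
#' @export
simulate_induction_measurements <- function(model,
                                            timepoints = cc_timepoints(),
                                            replicates = 3,
                                            noise_sd = 0.05,
                                            seed = 1) {
  stopifnot(inherits(model, "cc_induction_fit"))
  if (!length(timepoints)) stop("`timepoints` must be non-empty", call. = FALSE)
  if (any(timepoints < 0)) stop("`timepoints` must be nonnegative", call. = FALSE)
  stopifnot(replicates >= 1, noise_sd >= 0)
  mu <- induction_curve(model, timepoints)
  with_seed(seed, {
    tidyr::expand_grid(replicate = seq_len(replicates), time = timepoints) |>
      dplyr::mutate(
        ratio = pmax(rep(mu, replicates) +
                       stats::rnorm(dplyr::n(), 0, noise_sd), 0)
      ) |>
      dplyr::select("time", "replicate", "ratio")
  })
}

#' Simulate one site's normalized HA/Myc ratio series
#'
#' Forward model for a single chromatin site: the occupancy ratio
#' \eqn{\theta_B(t)/\theta_A(t)} is obtained from the mass-action turnover
#' ODEs at the site's true rates, transformed to the observed ratio scale by
#' the inverse of the background-subtraction/scaling step,
#' \eqn{R(t) = (X_{CC}/X_P)\,\theta_B(t)/\theta_A(t) + B}, then multiplied
#' by lognormal noise with the site's CV.
#'
#' @param truth A one-row data frame (or list) with `kd_true`, `kacA_true`,
#'   `XCC_true`, `B_true`, `noise_cv`, and optionally `site_id`.
#' @param induction A `cc_induction_fit`.
#' @param timepoints Sampling times in minutes.
#' @param seed Integer seed.
#' @return A tibble: `site_id`, `time`, `R_true` (noise-free), `R`.
#' @export
simulate_site_ratio_series <- function(truth, induction,
                                       timepoints = cc_timepoints(),
                                       seed = 1) {
  stopifnot(inherits(induction, "cc_induction_fit"))
  stopifnot(truth$kd_true > 0, truth$kacA_true > 0, truth$XCC_true > 0,
            truth$B_true >= 0, truth$noise_cv >= 0)
  sol <- solve_turnover_odes(truth$kacA_true, truth$kd_true, induction,
                             timepoints)
  theta <- sol$theta_ratio[match(timepoints, sol$time)]
  r_true <- (truth$XCC_true / induction$XP) * theta + truth$B_true
  noise <- with_seed(seed, lognormal_noise(length(r_true), truth$noise_cv))
  tibble::tibble(
    site_id = if (!is.null(truth$site_id)) truth$site_id else "site_1",
    time = timepoints,
    R_true = r_true,
    R = r_true * noise
  )
}

# mean-1 multiplicative lognormal noise with coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a complete competition-ChIP experiment with known truth
#'
#' Generates a full synthetic bundle for pipeline validation: per-site true
#' kinetic parameters, HA and Myc count matrices whose depth-normalized,
#' protein-scaled ratio has expectation equal to the true ratio signal, a
#' western-style protein calibration series, peak regions (BED-style,
#' 0-based half-open), a TSS annotation exercising the promoter-window
#' assignment rules (including off-window regions and tRNA genes), and a
#' per-gene mRNA synthesis-rate table.
#'
#' True residence times are drawn log-uniformly over `t_half_range`;
#' `kd_true = log(2) / t_half`. The effective on-rate `kacA_true` is drawn
#' log-uniformly over `kacA_range` (the observable is insensitive to it).
#' Per-site ratio amplitudes `XCC_true` are lognormal around `XP` and
#' backgrounds uniform on \[0.05, 0.3\]. HA columns carry injected
#' library-scale distortions that the protein-scaling normalization step
#' must remove.
#'
#' @param n_sites Number of sites (`>= 1`).
#' @param t_half_range Range of true residence times (min), sampled
#'   log-uniformly. Default `c(0.1, 30)`.
#' @param induction A `cc_induction_fit` describing competitor induction.
#' @param noise A `cc_noise_model`.
#' @param seed Integer seed; the full bundle is a pure function of the
#'   arguments.
#' @param timepoints Sampling times (min). Default [cc_timepoints()].
#' @param kacA_range Range for the true on-rate product (min^-1).
#' @param frac_in_window Fraction of peak regions placed inside the
#'   -250..+100 bp promoter window. Default 0.85.
#' @param frac_trna Fraction of genes annotated as tRNA. Default 0.05.
#' @param sample_counts Draw counts stochastically? With `FALSE` the exact
#'   expected (non-integer) counts are emitted, which makes the
#'   normalization round trip exact in the zero-noise limit.
#' @return A list of class `cc_experiment` with elements `truth`,
#'   `ha_counts`, `myc_counts` (tibbles, `site_id` + one column per time),
#'   `ratio` (long tibble `site_id`, `time`, `R_true`, `R`),
#'   `protein_ratio` (`time`, `ratio`: the calibration series used by
#'   HA-to-protein scaling), `ha_scale` (injected per-column distortions),
#'   `regions` (BED-style tibble), `annotation` (TSS table), and
#'   `synthesis_rates`.
#' @export
simulate_experiment <- function(n_sites,
                                t_half_range = c(0.1, 30),
                                induction = induction_model(),
                                noise = noise_model(),
                                seed = 1,
                                timepoints = cc_timepoints(),
                                kacA_range = c(0.5, 5),
                                frac_in_window = 0.85,
                                frac_trna = 0.05,
                                sample_counts = TRUE) {
  stopifnot(n_sites >= 1, inherits(noise, "cc_noise_model"),
            inherits(induction, "cc_induction_fit"))
  with_seed(seed, {
    ids <- sprintf("site_%04d", seq_len(n_sites))
    genes <- sprintf("gene_%04d", seq_len(n_sites))
    t_half_true <- exp(stats::runif(n_sites, log(t_half_range[1]),
                                    log(t_half_range[2])))
    truth <- tibble::tibble(
      site_id = ids,
      gene_id = genes,
      kd_true = log(2) / t_half_true,
      kacA_true = exp(stats::runif(n_sites, log(kacA_range[1]),
                                   log(kacA_range[2]))),
      XCC_true = induction$XP * stats::rlnorm(n_sites, 0, 0.25),
      B_true = stats::runif(n_sites, 0.05, 0.3),
      noise_cv = noise$ratio_noise
    )

    # noise-free and observed ratio signal per site
    ratio <- purrr::pmap_dfr(
      list(truth$site_id, truth$kacA_true, truth$kd_true,
           truth$XCC_true, truth$B_true),
      function(id, kacA, kd, XCC, B) {
        sol <- solve_turnover_odes(kacA, kd, induction, timepoints)
        theta <- sol$theta_ratio[match(timepoints, sol$time)]
        tibble::tibble(site_id = id, time = timepoints,
                       R_true = (XCC / induction$XP) * theta + B)
      })
    ratio$R <- ratio$R_true *
      lognormal_noise(nrow(ratio), noise$ratio_noise)

    # counts: Myc ~ depth x site enrichment; HA ~ Myc x R x column distortion
    n_t <- length(timepoints)
    enrich <- stats::rlnorm(n_sites, 0, 0.5)
    enrich <- enrich / mean(enrich)
    ha_scale <- stats::rlnorm(n_t, 0, 0.3)
    mu_myc <- matrix(noise$count_depth * enrich, n_sites, n_t)
    # ratio long table is site-major; reshape to sites x times
    r_obs <- t(matrix(ratio$R, nrow = n_t))
    mu_ha <- mu_myc * r_obs * matrix(ha_scale, n_sites, n_t, byrow = TRUE)
    draw <- function(mu) {
      if (!sample_counts) return(mu)
      if (noise$count_dispersion == 0) {
        matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
      } else {
        matrix(stats::rnbinom(length(mu), mu = mu,
                              size = 1 / noise$count_dispersion),
               nrow(mu), ncol(mu))
      }
    }
    as_count_tbl <- function(m) {
      colnames(m) <- sprintf("t_%g", timepoints)
      dplyr::bind_cols(tibble::tibble(site_id = ids), tibble::as_tibble(m))
    }
    ha_counts <- as_count_tbl(draw(mu_ha))
    myc_counts <- as_count_tbl(draw(mu_myc))

    # western-style calibration series consistent with the count model:
    # the genome-wide mean of the (noise-free) site ratios at each time
    protein_ratio <- ratio |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(ratio = mean(.data$R_true), .groups = "drop")

    # annotation and regions: genes on alternating strands, regions mostly
    # inside the promoter window, some decoys outside, a few tRNA genes
    tss <- 5000L * seq_len(n_sites) + 1000L
    strand <- rep(c("+", "-"), length.out = n_sites)
    biotype <- ifelse(stats::runif(n_sites) < frac_trna, "tRNA", "mRNA")
    in_window <- stats::runif(n_sites) < frac_in_window
    offset <- ifelse(in_window,
                     round(stats::runif(n_sites, -250, 100)),
                     sample(c(-1, 1), n_sites, replace = TRUE) *
                       round(stats::runif(n_sites, 400, 900)))
    tss0 <- tss - 1L
    mid <- ifelse(strand == "+", tss0 + offset, tss0 - offset)
    regions <- tibble::tibble(
      chrom = "chrI",
      start = as.integer(mid - 100),
      end = as.integer(mid + 100),
      site_id = ids
    )
    annotation <- tibble::tibble(
      gene_id = genes, chrom = "chrI", tss = as.integer(tss),
      strand = strand, biotype = biotype
    )
    synthesis_rates <- tibble::tibble(
      gene_id = genes,
      rate = stats::rlnorm(n_sites, log(0.05), 1)
    )
    truth$region_in_window <- in_window

    structure(
      list(truth = truth, ha_counts = ha_counts, myc_counts = myc_counts,
           ratio = ratio, protein_ratio = protein_ratio,
           ha_scale = tibble::tibble(time = timepoints, scale = ha_scale),
           regions = regions, annotation = annotation,
           synthesis_rates = synthesis_rates,
           induction = induction, timepoints = timepoints, seed = seed),
      class = "cc_experiment"
    )
  })
}

#' @export
print.cc_experiment <- function(x, ...) {
  cat("Synthetic competition-ChIP experiment:",
      nrow(x$truth), "sites,", length(x$timepoints), "time points, seed",
      x$seed, "\n")
  cat(sprintf("  true residence times %.2g-%.2g min\n",
              min(log(2) / x$truth$kd_true), max(log(2) / x$truth$kd_true)))
  invisible(x)
}
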