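#' Parameters for the synthetic counting-sheet generator
#'
#' The generator emulates the structure of manual hotspot-first Ki67
#' counting: each simulated cell is a Bernoulli draw whose success
#' probability follows a positivity profile that starts at the hotspot rate,
#' decays once counting leaves the hotspot, and settles at a background
#' rate (the dilution effect). Paired cohorts couple the surgical sample to
#' its core biopsy multiplicatively: the surgical hotspot rate is the
#' biopsy rate times a lognormal factor.
#'
#' Defaults describe a cohort in which the hotspot window reads in the
#' mid-20s percent, the background in the low 20s/high teens (so the
#' first-200 versus last-800 contrast lands near five percentage points),
#' roughly one third of tumors exceed the 20% cut-off, and the surgical
#' sample reads about 19% lower than its biopsy on the multiplicative
#' scale.
#'
#' @param p_hot Hotspot positive fraction of the reference profile (0--1).
#' @param p_bg Background positive fraction after the decay, `<= p_hot`.
#' @param hotspot_cells Cells counted before decay begins (multiple of 10).
#' @param decay_cells Cells over which positivity falls from `p_hot` to
#'   `p_bg`; `hotspot_cells + decay_cells` must not exceed 1000.
#' @param decay_shape `"linear"` (default), `"step"`, or `"exponential"`.
#' @param ratio_gm Geometric-mean surgical/biopsy rate ratio (default
#'   0.81).
#' @param ratio_sd_log Between-pair SD of the log ratio (default 0.6).
#' @param n_pairs Cohort size (default 50).
#' @param base_mu_logit,base_sd_logit Location and scale of the
#'   logit-normal between-tumor distribution of the biopsy hotspot rate.
#'   The defaults (`qlogis(0.16)`, 0.6) put roughly one third of tumors
#'   above a 20% hotspot rate.
#' @param reread_sd SD of the per-record observer effect (on the rate
#'   scale) when a slide is re-read; default 0.04.
#' @param reread_shift Systematic rate shift of a second read; default
#'   0.02.
#' @param seed RNG seed used by [generate_cohort()].
#' @return A validated list of class `"generator_params"`.
#' @export
generator_params <- function(p_hot = 0.255, p_bg = 0.202, hotspot_cells = 200,
                             decay_cells = 300,
                             decay_shape = c("linear", "step", "exponential"),
                             ratio_gm = 0.81, ratio_sd_log = 0.6, n_pairs = 50,
                             base_mu_logit = stats::qlogis(0.16),
                             base_sd_logit = 0.6,
                             reread_sd = 0.04, reread_shift = 0.02, seed = 1) {
  decay_shape <- match.arg(decay_shape)
  if (!(p_bg >= 0 && p_bg <= p_hot && p_hot <= 1)) {
    stop("need 0 <= p_bg <= p_hot <= 1", call. = FALSE)
  }
  if (p_hot == 0) stop("'p_hot' must be positive", call. = FALSE)
  if (hotspot_cells %% 10 != 0 || hotspot_cells < 0) {
    stop("'hotspot_cells' must be a non-negative multiple of 10", call. = FALSE)
  }
  if (decay_cells < 0 || hotspot_cells + decay_cells > 1000) {
    stop("'hotspot_cells' + 'decay_cells' must not exceed 1000", call. = FALSE)
  }
  if (ratio_gm <= 0 || ratio_sd_log < 0) {
    stop("'ratio_gm' must be positive and 'ratio_sd_log' non-negative", call. = FALSE)
  }
  if (n_pairs < 2) stop("'n_pairs' must be at least 2", call. = FALSE)
  if (reread_sd < 0) stop("'reread_sd' must be non-negative", call. = FALSE)
  structure(list(p_hot = p_hot, p_bg = p_bg, hotspot_cells = hotspot_cells,
                 decay_cells = decay_cells, decay_shape = decay_shape,
                 ratio_gm = ratio_gm, ratio_sd_log = ratio_sd_log,
                 n_pairs = as.integer(n_pairs), base_mu_logit = base_mu_logit,
                 base_sd_logit = base_sd_logit, reread_sd = reread_sd,
                 reread_shift = reread_shift, seed = as.integer(seed)),
            class = "generator_params")
}

#' Cell-wise positivity profile
#'
#' The per-cell positive probability along the counting order for a sample
#' whose hotspot rate is `base_p`. The reference profile (`p_hot` falling
#' to `p_bg`) is rescaled by `base_p / p_hot`, so `base_p` *is* the
#' sample's hotspot rate and the hotspot-to-background ratio is shared
#' across samples. Probabilities are clamped to [0, 1].
#'
#' @param params A [generator_params()] object.
#' @param base_p The sample's hotspot positive rate (default `p_hot`).
#' @param n_cells Profile length in cells (default 1000).
#' @return Numeric vector of length `n_cells`.
#' @export
rate_profile <- function(params, base_p = params$p_hot, n_cells = 1000) {
  stopifnot(inherits(params, "generator_params"))
  if (base_p < 0 || base_p > 1) stop("'base_p' must lie in [0, 1]", call. = FALSE)
  i <- seq_len(n_cells)
  hs <- params$hotspot_cells
  dc <- params$decay_cells
  ref <- rep(params$p_bg, n_cells)
  ref[i <= hs] <- params$p_hot
  if (dc > 0 && params$decay_shape != "step") {
    idx <- i > hs & i <= hs + dc
    t <- (i[idx] - hs) / dc
    ref[idx] <- switch(params$decay_shape,
      linear = params$p_hot + (params$p_bg - params$p_hot) * t,
      # decays to within ~5% of the gap at the end of the decay window
      exponential = params$p_bg + (params$p_hot - params$p_bg) * exp(-3 * t))
  }
  pmin(pmax(ref * base_p / params$p_hot, 0), 1)
}

#' Generate one synthetic counting record
#'
#' Draws `n_cells` independent Bernoulli cells along the positivity
#' profile of [rate_profile()] and aggregates them into 10-cell
#' increments. The underlying profile is attached as the `"rate"`
#' attribute so that duplicate reads can be re-drawn around it. Uses the
#' current RNG state; seed control belongs to [generate_cohort()] or the
#' caller.
#'
#' @inheritParams rate_profile
#' @param sample_type `"core_biopsy"` or `"surgical"`.
#' @param sample_id Identifier for the record.
#' @param round Evaluation round (default 1).
#' @param n_cells Cells to count (multiple of 10, at most 1000; default
#'   1000).
#' @return A [counting_record()] with attribute `"rate"`.
#' @export
generate_record <- function(params, sample_type = c("core_biopsy", "surgical"),
                            base_p = params$p_hot, sample_id = "sim",
                            round = 1L, n_cells = 1000) {
  sample_type <- match.arg(sample_type)
  stopifnot(inherits(params, "generator_params"))
  if (n_cells %% 10 != 0 || n_cells < 10 || n_cells > 1000) {
    stop("'n_cells' must be a multiple of 10 in [10, 1000]", call. = FALSE)
  }
  p <- rate_profile(params, base_p, n_cells)
  cells <- stats::rbinom(n_cells, 1L, p)
  inc <- as.integer(colSums(matrix(cells, nrow = 10L)))
  rec <- counting_record(sample_id, sample_type, round, inc)
  attr(rec, "rate") <- p
  rec
}

#' Generate a paired synthetic cohort
#'
#' Simulates `n_pairs` tumors. Each tumor's biopsy hotspot rate is drawn
#' from the logit-normal between-tumor distribution; the surgical hotspot
#' rate multiplies it by a lognormal factor with geometric mean `ratio_gm`
#' and log-SD `ratio_sd_log` (capped at 0.99). Both members then get full
#' counting records from [generate_record()]. Reproducible: the same
#' params (including `seed`) always yield the same cohort.
#'
#' @inheritParams rate_profile
#' @param n_cells Cells per record (default 1000).
#' @return List of [sample_pair()] objects, length `n_pairs`.
#' @examples
#' cohort <- generate_cohort(generator_params(n_pairs = 4, seed = 42), n_cells = 200)
#' cohort[[1]]
#' @export
generate_cohort <- function(params, n_cells = 1000) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  ids <- sprintf("P%03d", seq_len(params$n_pairs))
  lapply(ids, function(id) {
    base_b <- stats::plogis(stats::rnorm(1, params$base_mu_logit, params$base_sd_logit))
    ratio <- stats::rlnorm(1, log(params$ratio_gm), params$ratio_sd_log)
    base_s <- min(base_b * ratio, 0.99)
    sample_pair(id,
                generate_record(params, "core_biopsy", base_b, id, 1L, n_cells),
                generate_record(params, "surgical", base_s, id, 1L, n_cells))
  })
}

#' Generate a duplicate (second-round) read of a record
#'
#' Re-draws the increment counts of a generated record around its
#' underlying positivity profile plus a per-record observer effect drawn
#' from Normal(`shift`, `reread_sd`), modelling re-read variability of the
#' same slide: a second evaluation revisits the same tissue but not the
#' identical cells, with a possibly systematic shift of level.
#'
#' @param record A record produced by [generate_record()] (must carry the
#'   `"rate"` attribute).
#' @param reread_sd SD of the observer effect on the rate scale.
#' @param shift Mean of the observer effect (systematic second-read
#'   shift).
#' @param seed Optional seed for reproducibility of this single re-read.
#' @return A [counting_record()] with `round` incremented, carrying its
#'   own `"rate"` attribute.
#' @export
generate_duplicate_counts <- function(record, reread_sd = 0.04, shift = 0.02,
                                      seed = NULL) {
  stopifnot(inherits(record, "counting_record"))
  rate <- attr(record, "rate")
  if (is.null(rate)) {
    stop("record carries no underlying rate profile; only generated records can be re-read",
         call. = FALSE)
  }
  if (reread_sd < 0) stop("'reread_sd' must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eff <- stats::rnorm(1, shift, reread_sd)
  p2 <- pmin(pmax(rate + eff, 0), 1)
  cells <- stats::rbinom(length(p2), 1L, p2)
  inc <- as.integer(colSums(matrix(cells, nrow = 10L)))
  rec <- counting_record(record$sample_id, record$sample_type,
                         record$round + 1L, inc)
  attr(rec, "rate") <- p2
  rec
}
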