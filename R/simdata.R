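# Synthetic cohorts emulating the statistical structure of pretreatment
# rectal-cancer expression profiling: an extreme-response discovery design
# (pCR vs poor responders), full-range cohorts, batch-shifted validation
# cohorts, and survival cohorts whose hazard is linked to a latent
# signature score.

#' Simulation configuration
#'
#' Defaults emulate the discovery design of the study the package models:
#' 32 complete responders (TRG = 100 percent) vs 32 poor responders
#' (TRG < 45 percent), with a few hundred transcripts of which a small set is
#' differentially expressed between the classes.
#'
#' @param n_genes total number of transcripts.
#' @param n_informative number of transcripts shifted between classes (the
#'   planted signature; always the first `n_informative` genes).
#' @param n_positive,n_negative,n_intermediate class sizes. Positives carry
#'   TRG = 100, negatives TRG uniform on \[10, 44.9\], intermediates uniform
#'   on \[45, 99.9\].
#' @param effect_size mean log2 shift of informative genes in positives
#'   relative to negatives (Cohen's d = effect_size / noise_sd).
#' @param noise_sd within-class per-gene standard deviation on the log2 scale.
#' @param batch_shift additive per-cohort offset applied by
#'   [generate_validation_cohort()].
#' @param graded_effect if `TRUE`, the informative-gene shift scales linearly
#'   with TRG/100 instead of being a class-wise step, so classifier scores
#'   correlate with the full-range regression grade.
#' @param cohort_label label recorded in the annotation.
#' @param seed integer; fixes all randomness.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(n_genes = 500, n_informative = 10, n_positive = 32,
                       n_negative = 32, n_intermediate = 0, effect_size = 2,
                       noise_sd = 1, batch_shift = 0, graded_effect = FALSE,
                       cohort_label = "sim", seed = 1) {
  stopifnot(n_informative <= n_genes, effect_size >= 0, noise_sd > 0,
            n_positive >= 0, n_negative >= 0, n_intermediate >= 0)
  structure(list(n_genes = n_genes, n_informative = n_informative,
                 n_positive = n_positive, n_negative = n_negative,
                 n_intermediate = n_intermediate, effect_size = effect_size,
                 noise_sd = noise_sd, batch_shift = batch_shift,
                 graded_effect = graded_effect, cohort_label = cohort_label,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One master seed spawns independent substreams (gene means, TRG, noise,
# censoring) so that e.g. a validation cohort can reuse the reference's gene
# means while drawing fresh noise.
spawn_seeds <- function(seed, n = 4L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

sim_trg <- function(config) {
  c(rep(100, config$n_positive),
    runif(config$n_negative, 10, 44.9),
    runif(config$n_intermediate, 45, 99.9))
}

sim_expression <- function(config, gene_means, trg, sample_ids) {
  n <- length(trg)
  vals <- matrix(rnorm(config$n_genes * n, sd = config$noise_sd),
                 config$n_genes, n) + gene_means
  if (config$n_informative > 0L && config$effect_size > 0) {
    shift <- if (config$graded_effect) config$effect_size * trg / 100
             else config$effect_size * as.numeric(trg >= 100)
    idx <- seq_len(config$n_informative)
    vals[idx, ] <- vals[idx, ] + rep(shift, each = config$n_informative)
  }
  wid <- max(4L, nchar(config$n_genes))
  expression_matrix(vals,
                    probe_ids = sprintf("P%0*d", wid, seq_len(config$n_genes)),
                    gene_symbols = sprintf("G%0*d", wid, seq_len(config$n_genes)),
                    sample_ids = sample_ids)
}

#' Generate a synthetic cohort
#'
#' Baseline log2 intensities are Normal with per-gene means drawn once from
#' Uniform(6, 14) — the dynamic range of typical two-colour array data, kept
#' strictly positive so linear-scale ratio scores are well defined — and
#' within-class standard deviation `noise_sd`. The first `n_informative`
#' genes are shifted upward by `effect_size` in complete responders (or in
#' proportion to TRG under `graded_effect`). TRG is 100 for positives,
#' uniform on \[10, 44.9\] for negatives and \[45, 99.9\] for intermediates.
#'
#' @param config a [sim_config()].
#' @return A [cohort_bundle()]; per-gene baseline means and the planted gene
#'   set are attached as attributes `gene_means` and `informative_genes`.
#' @export
generate_cohort <- function(config) {
  seeds <- spawn_seeds(config$seed, 3L)
  set.seed(seeds[1L])
  gene_means <- runif(config$n_genes, 6, 14)
  set.seed(seeds[2L])
  trg <- sim_trg(config)
  n <- length(trg)
  if (n < 1L) stop("empty cohort")
  ids <- sprintf("%s_S%03d", config$cohort_label, seq_len(n))
  set.seed(seeds[3L])
  em <- sim_expression(config, gene_means, trg, ids)
  ann <- sample_annotation(ids, trg_percent = trg,
                           cohort_label = config$cohort_label)
  bundle <- cohort_bundle(em, ann)
  attr(bundle, "gene_means") <- gene_means
  attr(bundle, "informative_genes") <- em$probe_ids[seq_len(config$n_informative)]
  bundle
}

#' Generate a batch-shifted validation cohort
#'
#' Draws samples from the same generative model as `reference_bundle`
#' (identical per-gene baseline means and gene universe) and then adds the
#' additive batch offset `config$batch_shift` to every value — the distortion
#' that reference-anchored quantile alignment is designed to remove.
#'
#' @param config a [sim_config()]; its `seed` drives the new cohort's TRG and
#'   noise; `batch_shift` is applied to all values.
#' @param reference_bundle a bundle from [generate_cohort()] supplying the
#'   gene universe and baseline means.
#' @param sample_scale optional per-sample multiplicative factor (length 1 or
#'   number of samples) emulating per-array intensity scaling.
#' @return A [cohort_bundle()].
#' @export
generate_validation_cohort <- function(config, reference_bundle,
                                       sample_scale = 1) {
  gene_means <- attr(reference_bundle, "gene_means")
  if (is.null(gene_means) || length(gene_means) != config$n_genes ||
      config$n_genes != nrow(reference_bundle$expression$values))
    stop("gene universe of config does not match reference_bundle")
  seeds <- spawn_seeds(config$seed, 3L)
  set.seed(seeds[2L])
  trg <- sim_trg(config)
  n <- length(trg)
  ids <- sprintf("%s_V%03d", config$cohort_label, seq_len(n))
  set.seed(seeds[3L])
  em <- sim_expression(config, gene_means, trg, ids)
  vals <- (em$values + config$batch_shift) * rep(sample_scale, length.out = n)[col(em$values)]
  em <- expression_matrix(vals, reference_bundle$expression$probe_ids,
                          reference_bundle$expression$gene_symbols, ids)
  ann <- sample_annotation(ids, trg_percent = trg,
                           cohort_label = config$cohort_label)
  bundle <- cohort_bundle(em, ann)
  attr(bundle, "gene_means") <- gene_means
  attr(bundle, "informative_genes") <- attr(reference_bundle, "informative_genes")
  bundle
}

#' Generate a survival cohort linked to a latent signature score
#'
#' Each sample carries a latent standard-normal signature score `z`; the
#' informative genes are shifted by `effect_size * z` so that any sensible
#' expression score recovers `z`, and event times are exponential with hazard
#' proportional to `exp(-score_link_coefficient * z)` — high-score patients
#' live longer, the association a median-split log-rank analysis detects.
#' Censoring times are uniform on (0, u) with u calibrated on the drawn event
#' times so the expected censored fraction is `censor_rate`.
#'
#' @param n number of samples (>= 2).
#' @param score_link_coefficient strength of the score-hazard link; 0 gives a
#'   null cohort.
#' @param censor_rate target fraction of censored observations in \[0, 1).
#' @param seed integer seed.
#' @param n_genes,n_informative,effect_size,noise_sd expression model, as in
#'   [sim_config()].
#' @param base_hazard baseline exponential hazard (arbitrary time units).
#' @return A [cohort_bundle()] with `os_time`/`os_event` and
#'   `dfs_time`/`dfs_event` filled; the latent score is attached as attribute
#'   `latent_score`, the planted genes as `informative_genes`.
#' @export
generate_survival_cohort <- function(n, score_link_coefficient = 1,
                                     censor_rate = 0.3, seed = 1,
                                     n_genes = 100, n_informative = 10,
                                     effect_size = 1, noise_sd = 1,
                                     base_hazard = 0.1) {
  stopifnot(n >= 2, censor_rate >= 0, censor_rate < 1)
  seeds <- spawn_seeds(seed, 4L)
  set.seed(seeds[1L])
  gene_means <- runif(n_genes, 6, 14)
  set.seed(seeds[2L])
  z <- rnorm(n)
  set.seed(seeds[3L])
  vals <- matrix(rnorm(n_genes * n, sd = noise_sd), n_genes, n) + gene_means
  if (n_informative > 0L)
    vals[seq_len(n_informative), ] <- vals[seq_len(n_informative), ] +
      rep(effect_size * z, each = n_informative)
  wid <- max(4L, nchar(n_genes))
  ids <- sprintf("surv_S%04d", seq_len(n))
  em <- expression_matrix(vals, sprintf("P%0*d", wid, seq_len(n_genes)),
                          sprintf("G%0*d", wid, seq_len(n_genes)), ids)
  set.seed(seeds[4L])
  hazard <- base_hazard * exp(-score_link_coefficient * z)
  draw_endpoint <- function() {
    t_event <- rexp(n, rate = hazard)
    if (censor_rate == 0) return(list(time = t_event, event = rep(1, n)))
    # u such that E[min(T/u, 1)] = censor_rate on the drawn event times
    f <- function(u) mean(pmin(t_event / u, 1)) - censor_rate
    u <- uniroot(f, c(min(t_event) * 1e-6, max(t_event) * 1e6))$root
    cens <- runif(n, 0, u)
    list(time = pmin(t_event, cens), event = as.numeric(t_event <= cens))
  }
  os <- draw_endpoint()
  dfs <- draw_endpoint()
  ann <- sample_annotation(ids, cohort_label = "sim_survival",
                           os_time = os$time, os_event = os$event,
                           dfs_time = dfs$time, dfs_event = dfs$event)
  bundle <- cohort_bundle(em, ann)
  attr(bundle, "latent_score") <- z
  attr(bundle, "informative_genes") <- em$probe_ids[seq_len(n_informative)]
  bundle
}
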