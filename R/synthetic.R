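# Latent-factor multi-omics simulator: class-structured blocks (gaussian
# expression, beta-valued methylation, negative-binomial counts), survival
# times tied to the latent structure, and recorded ground truth, so the
# whole integration/classification/selection path is testable end to end.

#' Specification of one simulated omics block
#'
#' @param name block name (e.g. `"mrna"`, `"meth"`, `"mirna"`).
#' @param p number of features.
#' @param n_informative number of features carrying class signal
#'   (`n_informative <= p`).
#' @param kind one of `"gaussian"` (log-expression scale), `"beta"`
#'   (methylation beta values via inverse-logit, half the informative
#'   loadings sign-flipped so methylation anticorrelates with expression),
#'   or `"counts"` (negative-binomial counts with log-mean linear in the
#'   latent factors).
#' @param loading_scale magnitude of the informative loadings.
#' @param noise_sd standard deviation of the additive feature-level noise.
#' @param dispersion negative-binomial dispersion for `kind = "counts"`.
#' @return A `block_spec` list.
#' @export
block_spec <- function(name, p, n_informative, kind = c("gaussian", "beta", "counts"),
                       loading_scale = 1, noise_sd = 1, dispersion = 0.1) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, p >= 1L)
  if (n_informative > p) stop("n_informative must not exceed p")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(name = name, p = as.integer(p),
                 n_informative = as.integer(n_informative), kind = kind,
                 loading_scale = loading_scale, noise_sd = noise_sd,
                 dispersion = dispersion),
            class = "block_spec")
}

#' Simulation configuration for a multi-omics study
#'
#' @param n_per_class integer vector of class sizes (length `K >= 2`).
#' @param block_specs list of [block_spec()] objects.
#' @param class_separation nonnegative scale of the latent class-mean
#'   separation; 0 means no class signal anywhere.
#' @param survival list with `baseline_scale` (mean survival time at a null
#'   linear predictor), `effect_size` (log-hazard slope on the first latent
#'   axis) and `censor_fraction` in `[0, 1)`.
#' @param seed integer master seed for the draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_class = c(50L, 50L, 50L),
                       block_specs = list(
                         block_spec("mrna", 300L, 20L, "gaussian"),
                         block_spec("meth", 300L, 20L, "beta"),
                         block_spec("mirna", 300L, 20L, "gaussian")
                       ),
                       class_separation = 3,
                       survival = list(baseline_scale = 5, effect_size = 1,
                                       censor_fraction = 0.3),
                       seed = 1L) {
  if (any(n_per_class <= 0)) stop("class sizes must be positive")
  if (length(n_per_class) < 2L) stop("need at least 2 classes")
  if (class_separation < 0) stop("class_separation must be nonnegative")
  if (survival$censor_fraction < 0 || survival$censor_fraction >= 1) {
    stop("censor_fraction must be in [0, 1)")
  }
  if (survival$baseline_scale <= 0) stop("baseline_scale must be positive")
  nm <- vapply(block_specs, function(b) b$name, character(1L))
  if (anyDuplicated(nm)) stop("block names must be unique")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_classes = length(n_per_class),
                 block_specs = block_specs,
                 class_separation = class_separation,
                 survival = survival, seed = as.integer(seed)),
            class = "sim_config")
}

# Regular-simplex class means in K - 1 dimensions, scaled so the class
# means have unit variance along every latent axis (before multiplying by
# `separation`).
simplex_means <- function(K) {
  E <- diag(K) - 1 / K
  sv <- svd(E, nu = K - 1L, nv = 0L)
  M <- sv$u %*% diag(sv$d[seq_len(K - 1L)], K - 1L)
  sweep(M, 2L, sqrt(colMeans(M^2)), "/")
}

#' Generate latent class-structured factors
#'
#' Places the `K` class means at the vertices of a regular simplex in
#' `K - 1` dimensions, scaled so that each latent axis has class-mean
#' variance `separation^2`, and adds unit-variance within-class noise.
#'
#' @param n_per_class integer vector of class sizes.
#' @param separation nonnegative class-separation scale.
#' @param seed integer seed.
#' @return List with `latent` (`n x (K-1)` matrix) and `labels` (factor).
#' @export
generate_latent <- function(n_per_class, separation, seed) {
  if (any(n_per_class <= 0)) stop("class sizes must be positive")
  K <- length(n_per_class)
  if (K < 2L) stop("need at least 2 classes")
  if (separation < 0) stop("separation must be nonnegative")
  n <- sum(n_per_class)
  labels <- factor(rep(paste0("class", seq_len(K)), n_per_class))
  M <- simplex_means(K) * separation
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * (K - 1L)), n, K - 1L)
    latent <- M[as.integer(labels), , drop = FALSE] + Z
    rownames(latent) <- sprintf("S%03d", seq_len(n))
    names(labels) <- rownames(latent)
    list(latent = latent, labels = labels)
  })
}

#' Generate one omics block from latent factors
#'
#' Informative features load on a single latent axis (assigned round-robin)
#' with magnitude `loading_scale`; the rest are pure noise. `"beta"` blocks
#' pass the linear predictor through the inverse-logit (values strictly in
#' (0, 1)) with half the informative loadings sign-flipped; `"counts"`
#' blocks draw negative-binomial counts with log-mean linear in the latent
#' factors.
#'
#' @param latent `n x (K-1)` latent matrix from [generate_latent()].
#' @param spec a [block_spec()].
#' @param seed integer seed.
#' @return List with `x` (`n x p` matrix), `informative` (integer feature
#'   indices) and `loadings` (`p x (K-1)` matrix used).
#' @export
generate_block <- function(latent, spec, seed) {
  stopifnot(inherits(spec, "block_spec"))
  if (spec$noise_sd < 0) stop("noise_sd must be nonnegative")
  n <- nrow(latent)
  d <- ncol(latent)
  p <- spec$p
  with_seed(seed, {
    informative <- sort(sample.int(p, spec$n_informative))
    W <- matrix(0, p, d)
    if (spec$n_informative > 0L) {
      axes <- rep_len(seq_len(d), spec$n_informative)
      signs <- rep(1, spec$n_informative)
      if (spec$kind == "beta" && spec$n_informative > 1L) {
        # anticorrelate half the methylation features with the others
        signs[seq(2L, spec$n_informative, by = 2L)] <- -1
      }
      W[cbind(informative, axes)] <- spec$loading_scale * signs
    }
    eta <- latent %*% t(W)
    if (spec$noise_sd > 0) {
      eta <- eta + spec$noise_sd * matrix(stats::rnorm(n * p), n, p)
    }
    x <- switch(spec$kind,
      gaussian = eta,
      beta = stats::plogis(sweep(eta, 2L, stats::rnorm(p), "+")),
      counts = {
        base <- stats::runif(p, log(20), log(500))
        mu <- exp(sweep(eta, 2L, base, "+"))
        matrix(stats::rnbinom(n * p, mu = mu, size = 1 / spec$dispersion), n, p)
      }
    )
    colnames(x) <- sprintf("%s_f%04d", spec$name, seq_len(p))
    rownames(x) <- rownames(latent)
    list(x = x, informative = informative, loadings = W)
  })
}

#' Generate exponential survival with uniform censoring
#'
#' Event times are exponential with rate `exp(linear_predictor) /
#' baseline_scale`. Censoring times are uniform on `[0, c]` with `c` solved
#' numerically so that the expected censored fraction equals
#' `censor_fraction`.
#'
#' @param linear_predictor numeric vector of per-sample log-hazard shifts.
#' @param baseline_scale positive scale (mean time at zero predictor).
#' @param censor_fraction target censored fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return Data frame with `time` and `event` (1 = event, 0 = censored).
#' @export
generate_survival <- function(linear_predictor, baseline_scale,
                              censor_fraction, seed) {
  if (baseline_scale <= 0) stop("baseline_scale must be positive")
  if (censor_fraction < 0 || censor_fraction >= 1) {
    stop("censor_fraction must be in [0, 1)")
  }
  rate <- exp(linear_predictor) / baseline_scale
  with_seed(seed, {
    t_event <- stats::rexp(length(rate), rate = rate)
    if (censor_fraction == 0) {
      return(data.frame(time = t_event, event = 1L))
    }
    # P(censored | horizon c) for uniform censoring on [0, c]
    frac <- function(cc) mean((1 - exp(-rate * cc)) / (rate * cc)) - censor_fraction
    upper <- baseline_scale
    while (frac(upper) > 0) upper <- upper * 2
    cc <- stats::uniroot(frac, c(1e-8, upper))$root
    cens <- stats::runif(length(rate), 0, cc)
    data.frame(time = pmin(t_event, cens),
               event = as.integer(t_event <= cens))
  })
}

#' Generate a full synthetic multi-omics study
#'
#' Draws latent class factors, all configured omics blocks, and survival
#' outcomes, and records the ground-truth informative feature sets.
#'
#' @param config a [sim_config()].
#' @return A `multiomics_dataset`: list with `blocks` (named list of
#'   `n x p` matrices), `labels` (factor), `survival` (data frame with
#'   `sample_id`, `time`, `event`), `truth` (named list of informative
#'   feature names per block) and `config`.
#' @export
generate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  lat <- generate_latent(config$n_per_class, config$class_separation,
                         seed = config$seed + 1L)
  blocks <- list()
  truth <- list()
  for (q in seq_along(config$block_specs)) {
    spec <- config$block_specs[[q]]
    blk <- generate_block(lat$latent, spec, seed = config$seed + 10L + q)
    blocks[[spec$name]] <- blk$x
    truth[[spec$name]] <- colnames(blk$x)[blk$informative]
  }
  lp <- config$survival$effect_size *
    (lat$latent[, 1L] / stats::sd(lat$latent[, 1L]))
  surv <- generate_survival(lp, config$survival$baseline_scale,
                            config$survival$censor_fraction,
                            seed = config$seed + 99L)
  surv <- data.frame(sample_id = rownames(lat$latent), surv,
                     stringsAsFactors = FALSE)
  structure(list(blocks = blocks, labels = lat$labels, survival = surv,
                 truth = truth, config = config),
            class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat("Multi-omics dataset:", length(x$labels), "samples,",
      length(x$blocks), "block(s)\n")
  for (nm in names(x$blocks)) {
    cat(sprintf("  %-8s %5d features (%d informative)\n", nm,
                ncol(x$blocks[[nm]]),
                length(x$truth[[nm]] %||% character(0L))))
  }
  cat("Classes:", paste(sprintf("%s=%d", levels(x$labels),
                                tabulate(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a multi-omics dataset to disk
#'
#' One TSV per block (features in rows, samples in columns), a
#' `samples.tsv` table (sample_id, class, time, event) and a `truth.json`
#' with the informative feature names per block.
#'
#' @param dataset a `multiomics_dataset`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0L)
  for (nm in names(dataset$blocks)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    tab <- t(dataset$blocks[[nm]])
    utils::write.table(data.frame(feature = rownames(tab), tab,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  smp <- data.frame(sample_id = names(dataset$labels),
                    class = as.character(dataset$labels),
                    time = dataset$survival$time,
                    event = dataset$survival$event)
  sp <- file.path(dir, "samples.tsv")
  utils::write.table(smp, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(dataset$truth, tp, pretty = TRUE)
  invisible(c(paths, sp, tp))
}
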