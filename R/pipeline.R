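# End-to-end orchestration: simulate or load -> filter/intersect/split ->
# design -> tune -> fit -> evaluate -> consensus -> differential
# expression -> correlation/survival, with every artifact written to a run
# directory together with a manifest of parameters and seeds.

#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults: 70/30 stratified
#' split, 5 x 5 cross-validation, 30 consensus partitions, consensus
#' thresholds 15/0.05 and 10/0.2, `K - 1` components, and a single master
#' seed expanded per stage by fixed offsets.
#'
#' @param ... overrides of individual entries.
#' @return Named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    simulate = TRUE,             # use the built-in generator
    sim = NULL,                  # a sim_config(); default built at run time
    blocks = NULL,               # named list of TSV paths (features x samples)
    samples = NULL,              # samples.tsv path
    blacklist = NULL,            # optional feature-blacklist path
    count_block = NULL,          # name of the block holding raw counts
    unique_cutoff = 0.10, freq_ratio_cutoff = 19.0,
    train_frac = 0.7, folds = 5L, repeats = 5L,
    grid = c(5L, 10L, 20L, 40L), keepX = NULL, ncomp = NULL,
    n_partitions = 30L,
    f1 = 15, m1 = 0.05, f2 = 10, m2 = 0.2,
    min_cpm = 1, alpha = 0.05,
    seed = 1L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys override [default_config()] entries.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (simulate/load, preprocess, design,
#' tune, fit, evaluate, consensus, differential expression,
#' correlation/survival) and writes each artifact plus a `manifest.json`
#' recording parameters and seeds. A stage failure aborts with the stage
#' name; artifacts of completed stages are retained.
#'
#' @param config list from [default_config()] / [read_config()], or a YAML
#'   path.
#' @param out_dir output directory.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ds <- stage("input", {
    if (isTRUE(config$simulate)) {
      sim <- config$sim %||% sim_config(seed = seed)
      generate_study(sim)
    } else {
      if (is.null(config$blocks) || is.null(config$samples)) {
        stop("need 'blocks' paths and a 'samples' table")
      }
      blocks <- lapply(config$blocks, read_block)
      smp <- read_samples(config$samples)
      ix <- intersect_samples(blocks, smp)
      labels <- factor(ix$samples$class)
      names(labels) <- ix$samples$sample_id
      structure(list(blocks = ix$blocks, labels = labels,
                     survival = ix$samples[, intersect(c("sample_id", "time", "event"),
                                                       names(ix$samples))],
                     truth = list(), config = config),
                class = "multiomics_dataset")
    }
  })

  prep <- stage("preprocess", {
    blacklist <- if (!is.null(config$blacklist)) read_blacklist(config$blacklist)
      else character(0L)
    blocks <- lapply(ds$blocks, function(b) {
      keep <- setdiff(nzv_filter(b, config$unique_cutoff, config$freq_ratio_cutoff),
                      blacklist)
      b[, keep, drop = FALSE]
    })
    split <- stratified_split(stats::setNames(ds$labels, names(ds$labels)),
                              train_frac = config$train_frac, seed = seed + 11L)
    list(blocks = blocks, split = split)
  })

  # the count block feeds differential expression, not the CCA fit
  cca_names <- setdiff(names(prep$blocks), config$count_block)
  cca_blocks <- prep$blocks[cca_names]
  train <- match(prep$split$train, names(ds$labels))
  test <- match(prep$split$test, names(ds$labels))

  C <- stage("design", build_design(lapply(cca_blocks,
                                           function(b) b[train, , drop = FALSE])))
  utils::write.table(C, file.path(out_dir, "design.tsv"), sep = "\t", quote = FALSE)

  keepX <- config$keepX
  tuning <- NULL
  if (is.null(keepX)) {
    tuning <- stage("tune", {
      tune_keepX(lapply(cca_blocks, function(b) b[train, , drop = FALSE]),
                 ds$labels[train], grid = config$grid, ncomp = config$ncomp,
                 C = C, folds = config$folds, repeats = config$repeats,
                 seed = seed + 21L)
    })
    keepX <- tuning$keepX
    write_tsv(tuning$surface, file.path(out_dir, "tuning.tsv"))
  }

  model <- stage("fit", {
    sgcca(lapply(cca_blocks, function(b) b[train, , drop = FALSE]),
          ds$labels[train], keepX = keepX, ncomp = config$ncomp, C = C)
  })
  write_sgcca(model, file.path(out_dir, "model.json"))

  evaluation <- stage("evaluate", {
    pred <- predict(model, lapply(cca_blocks, function(b) b[test, , drop = FALSE]))
    metrics <- performance_metrics(ds$labels[test], pred$class)
    auc <- component_auc(model, pred$scores, ds$labels[test])
    votes <- data.frame(sample_id = prep$split$test,
                        true = as.character(ds$labels[test]),
                        as.data.frame(lapply(pred$block_class, as.character)),
                        final = as.character(pred$class))
    write_tsv(votes, file.path(out_dir, "predictions.tsv"))
    jsonlite::write_json(list(accuracy = metrics$accuracy,
                              per_class = metrics$per_class,
                              weights = as.list(model$weights),
                              auc = lapply(auc, function(m) as.data.frame(m)),
                              weight_rule = "mean over components of max |cor(score, dummy column)|"),
                         file.path(out_dir, "metrics.json"),
                         digits = NA, auto_unbox = TRUE)
    list(metrics = metrics, auc = auc, prediction = pred)
  })

  consensus <- stage("consensus", {
    cf <- consensus_fit(cca_blocks, ds$labels, keepX = keepX,
                        ncomp = model$ncomp, C = C,
                        n_partitions = config$n_partitions,
                        train_frac = config$train_frac, base_seed = seed + 31L)
    sel <- select_consensus(cf$records, config$f1, config$m1, config$f2, config$m2)
    write_tsv(sel, file.path(out_dir, "consensus.tsv"))
    list(fit = cf, selected = sel)
  })

  de <- NULL
  if (!is.null(config$count_block) && config$count_block %in% names(ds$blocks)) {
    de <- stage("dge", {
      counts <- t(ds$blocks[[config$count_block]])   # genes x samples
      levs <- levels(ds$labels)
      out <- list()
      for (i in seq_len(length(levs) - 1L)) {
        for (j in seq((i + 1L), length(levs))) {
          idx <- ds$labels %in% c(levs[i], levs[j])
          nm <- paste0(levs[i], "_vs_", levs[j])
          res <- de_contrast(counts[, idx, drop = FALSE],
                             factor(ds$labels[idx], levels = c(levs[i], levs[j])),
                             min_cpm = config$min_cpm, alpha = config$alpha)
          write_tsv(res[, c("gene", "logFC", "p", "fdr", "status")],
                    file.path(out_dir, paste0("de_", nm, ".tsv")))
          write_rnk(res, file.path(out_dir, paste0("de_", nm, ".rnk")))
          out[[nm]] <- res
        }
      }
      out
    })
  }

  surv <- NULL
  if (!is.null(ds$survival) && all(c("time", "event") %in% names(ds$survival))) {
    surv <- stage("survival", {
      sel_feats <- unique(consensus$selected$feature)
      exprs <- do.call(cbind, lapply(cca_blocks, function(b)
        b[, intersect(colnames(b), sel_feats), drop = FALSE]))
      res <- if (ncol(exprs) > 0L) {
        corr <- pearson_matrix(exprs)
        write_tsv(data.frame(feature = colnames(corr$r), corr$r,
                             check.names = FALSE),
                  file.path(out_dir, "correlation.tsv"))
        scr <- survival_screen(exprs, ds$survival$time, ds$survival$event)
        write_tsv(scr, file.path(out_dir, "survival.tsv"))
        list(correlation = corr, screen = scr)
      } else {
        NULL
      }
      res
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sgccaDA")),
    seed = seed,
    stage_seeds = list(split = seed + 11L, tune = seed + 21L,
                       consensus = seed + 31L),
    parameters = config[setdiff(names(config), c("sim", "blocks", "samples"))],
    keepX = keepX,
    artifacts = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(list(dataset = ds, design = C, tuning = tuning, model = model,
                 evaluation = evaluation, consensus = consensus, de = de,
                 survival = surv))
}
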