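# End-to-end orchestration: one config, one seed, plain-file stage outputs
# (CSV/JSON/PNG/TXT) with per-stage manifests so runs are resumable and
# inspectable.

PIPELINE_STAGES <- c("simulate", "preprocess", "decompose", "dfa", "features",
                     "reconstruct", "train-svm", "scalogram", "train-cnn",
                     "report")

#' Default pipeline configuration
#'
#' Every numeric default is the pipeline's reference setting: EEMD noise
#' ratio 0.01 with 100 realizations and 10 IMFs; DFA window grid from 0.1 to
#' 2 cycles with 30 log-spaced windows; reconstruction criteria alpha > 0.5,
#' R^2 > 0.9; screening gate p < 0.05; NCA weight cutoff 0.05; 5-fold
#' stratified CV; scalograms at 64 Morlet scales.
#'
#' @param out_dir Output directory for the run.
#' @param seed Single master seed for every stochastic stage.
#' @return Nested configuration list of class `vag_config`.
#' @export
default_config <- function(out_dir = "vag_run", seed = 1L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    input = list(manifest = NULL),
    synthetic = list(n_per_group = 20L, fs_hz = 4000, n_cycles = 10L,
                     cycle_s = 3, chain = "CKC", channels = "K1"),
    preprocess = list(n_cycles = 10L, cutoff_hz = 10, order = 4L,
                      zero_phase = FALSE),
    eemd = list(noise_ratio = 0.01, ensemble = 100L, max_imf = 10L),
    dfa = list(n_windows = 30L),
    reconstruct = list(alpha_min = 0.5, r2_min = 0.9),
    screening = list(alpha = 0.05, mc_reps = 2000L),
    nca = list(cutoff = 0.05),
    svm = list(k = 5L, cost = 1, gamma = "scale"),
    scalogram = list(n_scales = 64L, f_min = 5, resolution = 128L,
                     variants = c("a1", "a2", "raw")),
    cnn = list(filters = c(16L, 32L, 64L), dropout = 0.4, epochs = 30L,
               batch = 32L, l2 = 0.01, lr = 1e-3, hc_threshold = 0.7,
               variant = "a1", k = 5L)
  ), class = "vag_config")
}

#' Read a pipeline configuration from YAML
#'
#' Missing entries fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return A `vag_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        merge_in(base[[nm]], upd[[nm]])
      } else upd[[nm]]
    }
    base
  }
  out <- merge_in(unclass(cfg), user)
  class(out) <- "vag_config"
  out
}

stage_path <- function(cfg, stage, ...) {
  d <- file.path(cfg$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  file.path(d, ...)
}

write_stage_manifest <- function(cfg, stage, files, extra = NULL) {
  jsonlite::write_json(
    c(list(stage = stage, files = files, seed = cfg$seed,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra),
    stage_path(cfg, stage, "stage_manifest.json"), auto_unbox = TRUE)
}

#' Run the dual-path VAG pipeline
#'
#' Executes the requested stages in canonical order:
#' simulate -> preprocess -> decompose -> dfa -> features -> reconstruct ->
#' train-svm / scalogram -> train-cnn -> report. Each stage writes plain
#' files plus a stage manifest into `config$out_dir` and is skipped when not
#' requested; prerequisites are reloaded from an earlier run's outputs when
#' not in memory.
#'
#' @param config A `vag_config` (see [default_config()] / [read_config()]).
#' @param stages Stages to run (default: all).
#' @return The output directory, invisibly; stage results are also returned
#'   in the `results` attribute.
#' @export
run_pipeline <- function(config = default_config(), stages = PIPELINE_STAGES) {
  cfg <- config
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "run_config.yaml"))
  st <- new.env(parent = emptyenv())

  if (is.null(cfg$input$manifest) && !"simulate" %in% stages &&
      any(c("preprocess", "decompose") %in% stages) &&
      !file.exists(file.path(cfg$out_dir, "simulate", "manifest.csv"))) {
    abort("No input manifest configured and no simulated cohort found; nothing to preprocess.")
  }

  if ("simulate" %in% stages) {
    spec <- cohort_spec(n_per_group = cfg$synthetic$n_per_group,
                        fs_hz = cfg$synthetic$fs_hz,
                        n_cycles = cfg$synthetic$n_cycles,
                        cycle_s = cfg$synthetic$cycle_s,
                        chain = cfg$synthetic$chain,
                        channels = cfg$synthetic$channels,
                        profiles = cfg$synthetic$profiles %||% default_profiles(),
                        seed = cfg$seed)
    cohort <- generate_cohort(spec)
    man <- write_cohort(cohort, file.path(cfg$out_dir, "simulate"))
    st$recordings <- cohort$recordings
    st$manifest <- cohort$manifest
    write_stage_manifest(cfg, "simulate", basename(c(man, names(cohort$recordings))))
  }

  load_recordings <- function() {
    if (!is.null(st$recordings)) return(invisible())
    man_path <- cfg$input$manifest %||% file.path(cfg$out_dir, "simulate", "manifest.csv")
    if (!file.exists(man_path)) abort(sprintf("Manifest not found: '%s'.", man_path))
    man <- read_manifest(man_path)
    base_dir <- dirname(man_path)
    recs <- purrr::map(seq_len(nrow(man)), function(i) {
      p <- man$path[i]
      if (!file.exists(p)) p <- file.path(base_dir, p)
      read_recording(p, manifest_row = man[i, ])
    })
    names(recs) <- basename(man$path)
    st$recordings <- recs
    st$manifest <- man
  }

  if ("preprocess" %in% stages) {
    load_recordings()
    st$pre <- purrr::imap(st$recordings, function(rec, nm) {
      preprocess_recording(rec, n_cycles = cfg$preprocess$n_cycles,
                           cutoff_hz = cfg$preprocess$cutoff_hz,
                           zero_phase = cfg$preprocess$zero_phase)
    })
    files <- purrr::imap_chr(st$pre, function(pre, nm) {
      out <- stage_path(cfg, "preprocess", nm)
      write_recording(pre$samples, out)
      jsonlite::write_json(
        list(cycle_len = pre$cycle_len, flags = pre$flags,
             cycle_bounds = as.data.frame(pre$cycle_bounds),
             meta = unclass(pre$meta)),
        paste0(out, ".json"), auto_unbox = TRUE)
      basename(out)
    })
    write_stage_manifest(cfg, "preprocess", unname(files))
  }

  load_pre <- function() {
    if (!is.null(st$pre)) return(invisible())
    load_recordings()
    d <- file.path(cfg$out_dir, "preprocess")
    if (!dir.exists(d)) abort("Preprocess outputs not found; run the preprocess stage first.")
    st$pre <- purrr::imap(st$recordings, function(rec, nm) {
      side <- jsonlite::read_json(file.path(d, paste0(nm, ".json")), simplifyVector = TRUE)
      samples <- as.numeric(readLines(file.path(d, nm)))
      structure(list(samples = samples,
                     cycle_bounds = tibble::as_tibble(side$cycle_bounds),
                     cycle_len = side$cycle_len, meta = rec$meta,
                     flags = side$flags),
                class = "vag_preprocessed")
    })
  }

  if ("decompose" %in% stages) {
    load_pre()
    st$decomps <- purrr::imap(st$pre, function(pre, nm) {
      eemd(pre$samples, noise_ratio = cfg$eemd$noise_ratio,
           ensemble = cfg$eemd$ensemble, max_imf = cfg$eemd$max_imf,
           seed = derive_seed(cfg$seed, paste0("eemd:", nm)))
    })
    files <- purrr::imap_chr(st$decomps, function(d, nm) {
      out <- stage_path(cfg, "decompose", paste0(nm, ".imfs.tsv"))
      write_imf_matrix(d, out)
      basename(out)
    })
    write_stage_manifest(cfg, "decompose", unname(files))
  }

  load_decomps <- function() {
    if (!is.null(st$decomps)) return(invisible())
    load_pre()
    d <- file.path(cfg$out_dir, "decompose")
    if (!dir.exists(d)) abort("Decomposition outputs not found; run the decompose stage first.")
    st$decomps <- purrr::imap(st$pre, function(pre, nm) {
      m <- as.matrix(utils::read.table(file.path(d, paste0(nm, ".imfs.tsv"))))
      params <- jsonlite::read_json(file.path(d, paste0(nm, ".imfs.tsv.json")),
                                    simplifyVector = TRUE)
      imfs <- lapply(seq_len(nrow(m) - 1), function(i) as.numeric(m[i, ]))
      new_imf_decomposition(imfs, as.numeric(m[nrow(m), ]), as.list(params))
    })
  }

  if ("dfa" %in% stages) {
    load_decomps()
    st$fits <- purrr::imap(st$decomps, function(d, nm) {
      dfa_dual_imfs(d, st$pre[[nm]]$cycle_len, n_windows = cfg$dfa$n_windows)
    })
    tbl <- purrr::imap_dfr(st$fits, function(f, nm) {
      dplyr::mutate(dplyr::select(f, -"fit"), recording = nm, .before = 1)
    })
    out <- stage_path(cfg, "dfa", "dfa_fits.csv")
    utils::write.csv(tbl, out, row.names = FALSE)
    write_stage_manifest(cfg, "dfa", basename(out))
  }

  load_fits <- function() {
    if (!is.null(st$fits)) return(invisible())
    p <- file.path(cfg$out_dir, "dfa", "dfa_fits.csv")
    if (!file.exists(p)) abort("DFA outputs not found; run the dfa stage first.")
    tbl <- tibble::as_tibble(utils::read.csv(p))
    st$fits <- purrr::map(split(tbl, tbl$recording), function(g) {
      dplyr::select(g, -"recording")
    })[unique(tbl$recording)]
  }

  if ("features" %in% stages) {
    load_decomps(); load_fits()
    feats <- purrr::imap_dfr(st$decomps, function(d, nm) {
      pre <- st$pre[[nm]]
      rows <- imf_features(d, pre$meta$fs_hz)
      vec <- aggregate_band_features(rows, st$fits[[nm]])
      dplyr::bind_cols(
        tibble::tibble(recording = nm, subject_id = pre$meta$subject_id,
                       group = pre$meta$group, chain = pre$meta$chain,
                       channel = pre$meta$channel),
        tibble::as_tibble_row(as.list(vec)))
    })
    st$features <- feats
    out <- stage_path(cfg, "features", "feature_table.csv")
    utils::write.csv(feats, out, row.names = FALSE)
    scr <- screen_features(feats, alpha = cfg$screening$alpha,
                           mc_reps = cfg$screening$mc_reps,
                           seed = derive_seed(cfg$seed, "screening"))
    scr_out <- stage_path(cfg, "features", "screening.csv")
    utils::write.csv(scr, scr_out, row.names = FALSE)
    st$screening <- scr
    write_stage_manifest(cfg, "features", basename(c(out, scr_out)))
  }

  load_features <- function() {
    if (!is.null(st$features)) return(invisible())
    p <- file.path(cfg$out_dir, "features", "feature_table.csv")
    if (!file.exists(p)) abort("Feature table not found; run the features stage first.")
    st$features <- tibble::as_tibble(utils::read.csv(p))
    ps <- file.path(cfg$out_dir, "features", "screening.csv")
    if (file.exists(ps)) st$screening <- tibble::as_tibble(utils::read.csv(ps))
  }

  if ("reconstruct" %in% stages) {
    load_decomps(); load_fits()
    st$recon <- purrr::imap(st$decomps, function(d, nm) {
      reconstruct_pair(d, st$fits[[nm]], alpha_min = cfg$reconstruct$alpha_min,
                       r2_min = cfg$reconstruct$r2_min)
    })
    files <- purrr::imap(st$recon, function(rc, nm) {
      base <- sub("\\.txt$", "", nm)
      f1 <- stage_path(cfg, "reconstruct", paste0(base, "_a1.txt"))
      f2 <- stage_path(cfg, "reconstruct", paste0(base, "_a2.txt"))
      write_recording(rc$x_alpha1, f1)
      write_recording(rc$x_alpha2, f2)
      c(basename(f1), basename(f2))
    })
    incl <- purrr::imap_dfr(st$recon, function(rc, nm) {
      tibble::tibble(recording = nm,
                     included_local = paste(rc$included_local, collapse = ";"),
                     included_global = paste(rc$included_global, collapse = ";"),
                     empty_local = rc$empty_flags[["local"]],
                     empty_global = rc$empty_flags[["global"]])
    })
    inc_out <- stage_path(cfg, "reconstruct", "inclusion.csv")
    utils::write.csv(incl, inc_out, row.names = FALSE)
    write_stage_manifest(cfg, "reconstruct", c(unlist(files, use.names = FALSE),
                                               basename(inc_out)))
  }

  load_recon <- function() {
    if (!is.null(st$recon)) return(invisible())
    load_pre()
    d <- file.path(cfg$out_dir, "reconstruct")
    if (!dir.exists(d)) abort("Reconstructions not found; run the reconstruct stage first.")
    st$recon <- purrr::imap(st$pre, function(pre, nm) {
      base <- sub("\\.txt$", "", nm)
      list(x_alpha1 = as.numeric(readLines(file.path(d, paste0(base, "_a1.txt")))),
           x_alpha2 = as.numeric(readLines(file.path(d, paste0(base, "_a2.txt")))))
    })
  }

  results <- list()

  if ("train-svm" %in% stages) {
    load_features()
    feats <- st$features
    scr <- st$screening
    feat_cols <- intersect(FEATURE_NAMES, names(feats))
    keep_cols <- if (!is.null(scr)) scr$feature[scr$kept] else feat_cols
    if (length(keep_cols) < 2) keep_cols <- feat_cols
    X <- as.matrix(feats[, keep_cols, drop = FALSE])
    X[!is.finite(X)] <- 0
    nca <- nca_weights(scale(X), feats$group,
                       seed = derive_seed(cfg$seed, "nca"))
    sel <- select_by_weight(nca, cfg$nca$cutoff)
    rep <- svm_rbf_cv(X[, sel, drop = FALSE], feats$group, k = cfg$svm$k,
                      cost = cfg$svm$cost, gamma = cfg$svm$gamma,
                      seed = derive_seed(cfg$seed, "svm-folds"))
    utils::write.csv(rep$folds, stage_path(cfg, "train-svm", "fold_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$roc, stage_path(cfg, "train-svm", "roc_points.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$confusion, stage_path(cfg, "train-svm", "confusion.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(summary = rep$summary,
           nca_weights = stats::setNames(as.list(nca$weights), keep_cols),
           selected = keep_cols[sel]),
      stage_path(cfg, "train-svm", "summary.json"), auto_unbox = TRUE, digits = NA)
    results$svm <- rep
    write_stage_manifest(cfg, "train-svm",
                         c("fold_metrics.csv", "roc_points.csv", "confusion.csv",
                           "summary.json"))
  }

  if ("scalogram" %in% stages) {
    load_pre(); load_recon()
    fs <- st$pre[[1]]$meta$fs_hz
    grid <- scale_grid(fs, n_scales = cfg$scalogram$n_scales,
                       f_min = cfg$scalogram$f_min)
    res <- cfg$scalogram$resolution
    st$images <- list()
    files <- character(0)
    for (nm in names(st$pre)) {
      base <- sub("\\.txt$", "", nm)
      sig <- list(raw = st$pre[[nm]]$samples,
                  a1 = st$recon[[nm]]$x_alpha1,
                  a2 = st$recon[[nm]]$x_alpha2)
      for (v in cfg$scalogram$variants) {
        sid <- sprintf("%s_%s_%d", base, v, res)
        x <- sig[[v]]
        img <- if (stats::sd(x) == 0) {
          to_rgb_image(matrix(0, cfg$scalogram$n_scales, 256), res,
                       source_id = sid, grid_hash = grid$hash)
        } else {
          signal_scalogram(x, grid, resolution = res, source_id = sid)
        }
        st$images[[sid]] <- img
        f <- stage_path(cfg, "scalogram", paste0(sid, ".png"))
        write_scalogram_png(img, f)
        files <- c(files, basename(f))
      }
    }
    write_stage_manifest(cfg, "scalogram", files,
                         extra = list(grid_hash = grid$hash))
  }

  if ("train-cnn" %in% stages) {
    if (is.null(st$images)) {
      d <- file.path(cfg$out_dir, "scalogram")
      if (!dir.exists(d)) abort("Scalograms not found; run the scalogram stage first.")
      pngs <- list.files(d, pattern = "\\.png$", full.names = TRUE)
      st$images <- purrr::map(pngs, \(p) png::readPNG(p))
      names(st$images) <- sub("\\.png$", "", basename(pngs))
    }
    variant <- cfg$cnn$variant
    pick <- grepl(sprintf("_%s_%d$", variant, cfg$scalogram$resolution),
                  names(st$images))
    imgs <- st$images[pick]
    labs <- sub("_.*$", "", names(imgs))
    ccfg <- cnn_config(filters = cfg$cnn$filters, dropout = cfg$cnn$dropout,
                       epochs = cfg$cnn$epochs, batch = cfg$cnn$batch,
                       l2 = cfg$cnn$l2, lr = cfg$cnn$lr,
                       hc_threshold = cfg$cnn$hc_threshold,
                       seed = derive_seed(cfg$seed, "cnn"))
    rep <- cnn_train_cv(imgs, labs, config = ccfg, k = cfg$cnn$k)
    utils::write.csv(rep$folds, stage_path(cfg, "train-cnn", "fold_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$roc, stage_path(cfg, "train-cnn", "roc_points.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$confusion, stage_path(cfg, "train-cnn", "confusion.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(summary = rep$summary, variant = variant),
                         stage_path(cfg, "train-cnn", "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    results$cnn <- rep
    write_stage_manifest(cfg, "train-cnn",
                         c("fold_metrics.csv", "roc_points.csv", "confusion.csv",
                           "summary.json"))
  }

  if ("report" %in% stages) {
    summ <- list(config = unclass(cfg))
    for (nm in names(results)) {
      summ[[nm]] <- results[[nm]]$summary
    }
    jsonlite::write_json(summ, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  out <- cfg$out_dir
  attr(out, "results") <- results
  invisible(out)
}
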