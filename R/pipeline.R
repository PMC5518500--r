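# End-to-end orchestration (prepare -> select -> train -> super-resolve ->
# evaluate) and the command-line front end.

#' Default pipeline configuration
#'
#' A fully serializable nested list of every knob the pipeline uses. The
#' defaults run a compact, self-contained experiment on synthetic fixtures:
#' a pool of textured/flat images whose first `n_refs` members double as the
#' target-domain reference images (so selection has genuinely related
#' content to find), SIFT-based candidate selection, paired training data,
#' a small hybrid network, and a PSNR comparison of the trained network
#' against the template-only (bicubic) baseline on a held-out image.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir optional directory for artifacts (model JSON, report).
#' @return A named list (class `pipeline_config`).
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = NULL) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    fixtures = list(n_pool = 8L, n_refs = 2L, height = 96L, width = 96L),
    selection = list(enabled = TRUE, size = 64L, stride = 32L, ratio = 0.8,
                     octaves = 1L, sigma0 = 1.2, contrast_threshold = 0.02),
    data = list(crop_size = 32L, n_pairs = 40L, factor = 4L),
    network = list(f2 = 5L, n2 = 16L, n3 = 8L, f3 = 3L, init = "identity",
                   sd = 1e-3),
    training = list(epochs = 30L, learning_rate = 0.1, batch_size = 10L,
                    momentum = 0)
  ), class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full super-resolution pipeline
#'
#' Executes the flow: synthetic corpus generation, SIFT transfer selection
#' of training subregions, paired training-set construction, network
#' training, and held-out evaluation (trained network vs the template-layer
#' bicubic baseline). Every stage is seeded from `config$seed`; the report
#' embeds the resolved configuration.
#'
#' @param config a [default_pipeline_config()]-style list.
#' @return A run report: per-stage metrics, seeds, artifact paths, the
#'   trained network (`model`), and the resolved config.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  stopifnot(is.list(config), !is.null(config$seed))
  seed <- as.integer(config$seed)
  report <- list(config = config[setdiff(names(config), "out_dir")],
                 seed = seed, stages = list())

  pool_specs <- NULL
  refs <- NULL
  corpus <- pipeline_stage("fixtures", {
    fx <- config$fixtures
    if (is.null(fx)) stop("config$fixtures missing")
    pool_specs <- default_corpus_specs(fx$n_pool, fx$height, fx$width,
                                        seed = seed * 100L)
    pool <- lapply(pool_specs, generate_fixture)
    names(pool) <- sprintf("pool_%02d", seq_along(pool))
    # the target-domain references are the first n_refs pool members:
    # selection should recover exactly the subregions related to them
    refs <- pool[seq_len(min(fx$n_refs, length(pool)))]
    names(refs) <- sprintf("ref_%02d", seq_along(refs))
    pool
  })
  report$stages$fixtures <- list(n_pool = length(corpus), n_refs = length(refs))

  training_images <- pipeline_stage("select", {
    sel <- config$selection
    if (is.null(sel) || !isTRUE(sel$enabled)) {
      report$stages$select <- list(skipped = TRUE)
      corpus
    } else {
      s0 <- if (is.null(sel$sigma0)) 1.6 else sel$sigma0
      ref_fs <- lapply(names(refs), function(nm) {
        sift_features(refs[[nm]], nm, octaves = sel$octaves, sigma0 = s0,
                      contrast_threshold = sel$contrast_threshold)
      })
      cands <- list(); cand_imgs <- list()
      for (nm in names(corpus)) {
        crops <- tile_crops(corpus[[nm]], sel$size, sel$stride)
        for (ci in seq_along(crops)) {
          id <- sprintf("%s_crop%02d", nm, ci)
          cands[[id]] <- sift_features(crops[[ci]], id, octaves = sel$octaves,
                                       sigma0 = s0,
                                       contrast_threshold = sel$contrast_threshold)
          cand_imgs[[id]] <- crops[[ci]]
        }
      }
      dec <- select_candidates(cands, ref_fs, ratio = sel$ratio)
      report$stages$select <- list(
        n_candidates = nrow(dec), n_admitted = sum(dec$admitted),
        decisions = dec)
      adm <- cand_imgs[dec$candidate_id[dec$admitted]]
      if (!length(adm)) stop("no candidate subregion was admitted")
      adm
    }
  })

  pairs <- pipeline_stage("prepare", {
    d <- config$data
    patches <- crop_patches(training_images, size = d$crop_size,
                            count = d$n_pairs, seed = seed + 1L)
    make_pairs(patches, factor = d$factor)
  })
  report$stages$prepare <- list(n_pairs = length(pairs),
                                hr_size = config$data$crop_size)

  net <- pipeline_stage("train", {
    nw <- config$network; tr <- config$training
    net <- hybrid_network(f2 = nw$f2, n2 = nw$n2, n3 = nw$n3, f3 = nw$f3,
                          init = nw$init, sd = nw$sd, seed = seed + 2L)
    train_network(net, pairs, epochs = tr$epochs,
                  learning_rate = tr$learning_rate,
                  batch_size = tr$batch_size,
                  momentum = tr$momentum, seed = seed + 3L)
  })
  report$stages$train <- list(
    epochs = length(net$loss_history),
    initial_loss = net$initial_loss,
    final_loss = utils::tail(net$loss_history, 1))

  report$stages$evaluate <- pipeline_stage("evaluate", {
    fx <- config$fixtures
    held <- generate_fixture(fixture_spec("smooth_noise", 64, 64,
                                          seed = seed * 100L + 99L))
    p_net <- evaluate_sr(held, function(lr) super_resolve(net, lr))
    p_bic <- evaluate_sr(held, function(lr) {
      pmin(pmax(upscale4(lr, net$bank, rounding = "none"), 0), 1)
    })
    list(psnr_network_db = p_net$psnr_db, psnr_bicubic_db = p_bic$psnr_db,
         psnr_gain_db = p_net$psnr_db - p_bic$psnr_db)
  })

  report$model <- net
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    save_model(net, file.path(config$out_dir, "model.json"))
    rep_json <- report
    rep_json$model <- NULL
    rep_json$stages$select$decisions <- NULL
    jsonlite::write_json(rep_json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    report$artifacts <- list(
      model = file.path(config$out_dir, "model.json"),
      report = file.path(config$out_dir, "report.json"))
  }
  report
}

# ---- command-line front end -------------------------------------------------

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[[i + 1L]]; i <- i + 2L
    }
  }
  out
}

flag_num <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}

#' Command-line entry point
#'
#' Dispatches the subcommands `derive-templates`, `upscale`,
#' `make-fixtures`, `prepare-data`, `select-transfer`, `train`,
#' `super-resolve`, `evaluate` and `run-pipeline`. Installed as a thin
#' Rscript wrapper (`system.file("cli", "srr.R", package = "medsrr")`).
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status 0 invisibly; errors propagate.
#' @export
srr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: srr.R <derive-templates|upscale|make-fixtures|prepare-data|",
        "select-transfer|train|super-resolve|evaluate|run-pipeline> [--flags]\n",
        sep = "")
    return(invisible(1L))
  }
  cmd <- args[[1]]
  flags <- parse_flags(args[-1])
  switch(cmd,
    "derive-templates" = {
      write_template_bank(build_template_bank(), flags$out)
      message("wrote 16 templates to ", flags$out)
    },
    "upscale" = {
      img <- read_image(flags[["in"]], scale = "integer")
      up <- upscale4(img, build_template_bank(),
                     rounding = if (isTRUE(flags[["no-clamp"]])) "none"
                                else "integer",
                     border = if (is.null(flags$border)) "replicate"
                              else flags$border)
      write_image(up, flags$out)
    },
    "make-fixtures" = {
      specs <- if (!is.null(flags$spec)) {
        raw <- jsonlite::read_json(flags$spec, simplifyVector = FALSE)
        lapply(raw, function(s) {
          fixture_spec(s$kind, s$height, s$width,
                       params = if (is.null(s$params)) list() else s$params,
                       seed = if (is.null(s$seed)) 1L else s$seed)
        })
      } else {
        default_corpus_specs(n = flag_num(flags, "n", 8),
                             seed = flag_num(flags, "seed", 100))
      }
      generate_corpus(specs, flags$out)
    },
    "prepare-data" = {
      files <- list.files(flags$corpus, pattern = "\\.(png|tiff?)$",
                          full.names = TRUE)
      imgs <- lapply(files, read_image, scale = "integer")
      names(imgs) <- basename(files)
      patches <- crop_patches(imgs, size = flag_num(flags, "size", 128),
                              count = flag_num(flags, "n", 100),
                              seed = flag_num(flags, "seed", 7))
      pairs <- make_pairs(patches, factor = flag_num(flags, "factor", 4))
      dir.create(flags$out, showWarnings = FALSE, recursive = TRUE)
      manifest <- lapply(seq_along(pairs), function(i) {
        pr <- pairs[[i]]
        lr_f <- sprintf("pair_%05d_lr.png", i)
        hr_f <- sprintf("pair_%05d_hr.png", i)
        write_image(pr$lr, file.path(flags$out, lr_f))
        write_image(pr$hr, file.path(flags$out, hr_f))
        list(lr = lr_f, hr = hr_f, source_id = pr$source_id,
             crop_origin = pr$crop_origin, seed = pr$seed)
      })
      jsonlite::write_json(manifest, file.path(flags$out, "pairs.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    "select-transfer" = {
      pool_files <- list.files(flags$pool, pattern = "\\.(png|tiff?)$",
                               full.names = TRUE)
      ref_files <- list.files(flags$refs, pattern = "\\.(png|tiff?)$",
                              full.names = TRUE)
      refs <- lapply(ref_files, function(f)
        sift_features(read_image(f), basename(f)))
      cands <- list(); boxes <- list()
      for (f in pool_files) {
        img <- read_image(f)
        crops <- tile_crops(img, size = flag_num(flags, "size", 128),
                            stride = flag_num(flags, "stride", 64))
        for (ci in seq_along(crops)) {
          id <- sprintf("%s#%d", basename(f), ci)
          cands[[id]] <- sift_features(crops[[ci]], id)
          boxes[[id]] <- list(source = f, box = attr(crops[[ci]], "box"))
        }
      }
      dec <- select_candidates(cands, refs)
      adm <- dec[dec$admitted, , drop = FALSE]
      manifest <- lapply(seq_len(nrow(adm)), function(i) {
        id <- adm$candidate_id[i]
        c(boxes[[id]], list(D = adm$D[i], eta = adm$eta[i]))
      })
      jsonlite::write_json(manifest, flags$out, auto_unbox = TRUE, digits = NA)
      message(sprintf("admitted %d of %d candidates", nrow(adm), nrow(dec)))
    },
    "train" = {
      prs <- jsonlite::read_json(file.path(flags$pairs, "pairs.json"),
                                 simplifyVector = FALSE)
      pairs <- lapply(prs, function(p) {
        list(lr = read_image(file.path(flags$pairs, p$lr)),
             hr = read_image(file.path(flags$pairs, p$hr)))
      })
      cfg <- if (!is.null(flags$config))
        jsonlite::read_json(flags$config, simplifyVector = TRUE) else list()
      g <- function(nm, d) if (is.null(cfg[[nm]])) d else cfg[[nm]]
      net <- hybrid_network(f2 = g("f2", 5), n2 = g("n2", 16),
                            n3 = g("n3", 8), f3 = g("f3", 3),
                            init = g("init", "identity"),
                            seed = g("seed", 1))
      net <- train_network(net, pairs, epochs = g("epochs", 50),
                           learning_rate = g("learning_rate", 0.1),
                           batch_size = g("batch_size", 10),
                           seed = g("seed", 1))
      save_model(net, flags$out)
    },
    "super-resolve" = {
      net <- load_model(flags$model)
      lr <- read_image(flags[["in"]])
      write_image(super_resolve(net, lr), flags$out)
    },
    "evaluate" = {
      ref <- read_image(flags$ref)
      test <- read_image(flags$test)
      res <- if (!is.null(flags$regions)) {
        regs <- jsonlite::read_json(flags$regions, simplifyVector = FALSE)
        regs <- lapply(regs, function(r) region_spec(r$label, unlist(r$box)))
        region_psnr(ref, test, regs)
      } else {
        p <- psnr(ref, test)
        data.frame(label = "whole", mse = p$mse, psnr_db = p$psnr_db)
      }
      jsonlite::write_json(res, flags$out, auto_unbox = TRUE, digits = NA)
    },
    "run-pipeline" = {
      cfg <- default_pipeline_config(seed = flag_num(flags, "seed", 1),
                                     out_dir = flags$out)
      if (!is.null(flags$config)) {
        user <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
        cfg[names(user)] <- user
      }
      rep <- run_pipeline(cfg)
      message(sprintf("pipeline done: PSNR net %.2f dB vs bicubic %.2f dB",
                      rep$stages$evaluate$psnr_network_db,
                      rep$stages$evaluate$psnr_bicubic_db))
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
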