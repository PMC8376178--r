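#' Ingest a point-annotation table
#'
#' Reads an annotation CSV and maps it to the canonical schema
#' `annotation_id, worker_id, image_id, x, y` through a dialect adapter.
#' The default `"quantius"` dialect expects exactly those columns (extra
#' columns are ignored). New sources plug in by registering a column
#' mapping. Rows with missing, non-numeric or out-of-range coordinates
#' are dropped and counted.
#'
#' @param path CSV file path.
#' @param dialect Dialect name (`"quantius"`) or a named character vector
#'   mapping canonical names to source column names, e.g.
#'   `c(worker_id = "user", x = "col", y = "row")`.
#' @param image_width,image_height Optional bounds; when given,
#'   out-of-range coordinates are dropped.
#' @return Data frame of class `annotation_set`; attribute `"n_dropped"`
#'   counts discarded rows.
#' @export
ingest_annotations <- function(path, dialect = "quantius",
                               image_width = NULL, image_height = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  mapping <- if (is.character(dialect) && length(dialect) == 1L) {
    if (dialect != "quantius") {
      stop("unknown annotation dialect: ", dialect, call. = FALSE)
    }
    c(annotation_id = "annotation_id", worker_id = "worker_id",
      image_id = "image_id", x = "x", y = "y")
  } else if (is.character(dialect) && !is.null(names(dialect))) {
    base <- c(annotation_id = "annotation_id", worker_id = "worker_id",
              image_id = "image_id", x = "x", y = "y")
    base[names(dialect)] <- dialect
    base
  } else {
    stop("`dialect` must be a dialect name or a named column mapping",
         call. = FALSE)
  }
  required <- c("worker_id", "x", "y")
  missing_cols <- setdiff(mapping[required], names(raw))
  if (length(missing_cols) > 0L) {
    stop("annotation file is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    annotation_id = if (mapping[["annotation_id"]] %in% names(raw)) {
      as.character(raw[[mapping[["annotation_id"]]]])
    } else {
      sprintf("a%05d", seq_len(nrow(raw)))
    },
    worker_id = as.character(raw[[mapping[["worker_id"]]]]),
    image_id = if (mapping[["image_id"]] %in% names(raw)) {
      as.character(raw[[mapping[["image_id"]]]])
    } else {
      "img"
    },
    x = suppressWarnings(as.numeric(raw[[mapping[["x"]]]])),
    y = suppressWarnings(as.numeric(raw[[mapping[["y"]]]])),
    stringsAsFactors = FALSE)
  ok <- is.finite(out$x) & is.finite(out$y)
  if (!is.null(image_width)) ok <- ok & out$x >= 0 & out$x < image_width
  if (!is.null(image_height)) ok <- ok & out$y >= 0 & out$y < image_height
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(n_dropped, " annotation row(s) dropped (invalid coordinates)")
  }
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_set", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration of an end-to-end run. Every
#' section mirrors one stage's parameters; unknown keys are rejected so
#' typos fail before execution rather than silently using defaults.
#'
#' @param simulation Named list of [synth_config()] overrides, plus
#'   optional `width`, `height`.
#' @param worker Named list of [worker_model()] overrides, plus optional
#'   `n_workers`.
#' @param preprocessing Named list: `highpass_sigma`.
#' @param guidelines Named list of [guidelines()] overrides, plus optional
#'   `display_width`.
#' @param qc Named list of [run_qc()] overrides.
#' @param tuning Named list: `grid`, `min_distance`.
#' @param evaluation Named list: `threshold` (correctness radius),
#'   `dedup_radius`.
#' @param seed Global integer seed.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = list(), worker = list(),
                            preprocessing = list(), guidelines = list(),
                            qc = list(), tuning = list(),
                            evaluation = list(), seed = 1L,
                            out_dir = tempfile("crowdspot_run_")) {
  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0L) {
      stop(sprintf("unknown key(s) in config section `%s`: %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    x
  }
  # arguments shadow the package functions of the same name; fetch the
  # functions explicitly when listing their formals
  fml <- function(fn) names(formals(get(fn, mode = "function",
                                        envir = asNamespace("crowdspot"))))
  cfg <- list(
    simulation = check_keys(simulation, c(fml("synth_config"), "width",
                                          "height"), "simulation"),
    worker = check_keys(worker, c(fml("worker_model"), "n_workers"),
                        "worker"),
    preprocessing = check_keys(preprocessing, "highpass_sigma",
                               "preprocessing"),
    guidelines = check_keys(guidelines, c(fml("guidelines"), "display_width"),
                            "guidelines"),
    qc = check_keys(qc, setdiff(fml("run_qc"), "annos"), "qc"),
    tuning = check_keys(tuning, c("grid", "min_distance"), "tuning"),
    evaluation = check_keys(evaluation, c("threshold", "dedup_radius"),
                            "evaluation"),
    seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full simulate-annotate-QC-tune pipeline
#'
#' End-to-end orchestration on a synthetic image: simulate the image,
#' pre-process and first-pass detect, subdivide into annotatable crops,
#' simulate a crowd on every crop, run annotation QC per crop, reassemble
#' the consensus into the parent frame, tune the peak finder against the
#' consensus, and evaluate consensus and tuned detector against the
#' simulation truth. All artifacts (images, CSVs, JSON reports and the
#' run manifest) are written under `config$out_dir`; the fully-resolved
#' configuration is stored next to the outputs so every file is
#' reproducible from the manifest.
#'
#' @param config A [pipeline_config()].
#' @param write_images Write TIFF/PNG artifacts (disable for speed).
#' @return List of class `pipeline_run`: `manifest` (file paths and
#'   settings), `truth`, `consensus`, `tuning`, `evaluation`.
#' @export
run_pipeline <- function(config = pipeline_config(), write_images = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  sim_args <- config$simulation
  width <- sim_args$width %||% 300L; height <- sim_args$height %||% 300L
  sim_args$width <- NULL; sim_args$height <- NULL
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  sc <- do.call(synth_config, sim_args)
  sim <- simulate_spot_image(sc, width = width, height = height)

  hp <- config$preprocessing$highpass_sigma %||%
    (3 * max(rep_len(sc$sigma, max(1, sc$n_spots))))
  filtered <- preprocess_stack(sim$image, highpass_sigma = hp)

  # parameter extraction from a small "expert" sample of the truth, then
  # first-pass detection with the extracted parameters
  expert <- with_seed(derive_seed(seed, "expert"), {
    n <- nrow(sim$truth)
    sim$truth[sample.int(n, min(20L, n)), c("x", "y"), drop = FALSE]
  })
  params <- extract_spot_params(sim$image, expert)
  first_pass <- detect_spots(sim$image, params)

  gl_args <- config$guidelines
  display_width <- gl_args$display_width %||% 450L
  gl_args$display_width <- NULL
  gl <- do.call(guidelines, gl_args)
  crops <- recursive_subdivide(sim$image, first_pass, gl,
                               display_width = display_width)
  manifest_df <- crop_manifest(crops)

  wk_args <- config$worker
  n_workers <- wk_args$n_workers %||% 25L
  wk_args$n_workers <- NULL
  model <- do.call(worker_model, wk_args)

  ev <- config$evaluation
  threshold <- ev$threshold %||% 4
  dedup_radius <- ev$dedup_radius %||% 2

  consensus_by_crop <- list()
  annos_all <- list()
  for (cr in crops) {
    sp <- cr$spec
    truth_crop <- map_to_crop(sp, sim$truth)
    kept <- attr(truth_crop, "kept")
    truth_crop$sigma <- sim$truth$sigma[kept] * sp$scale
    truth_crop$snr <- sim$truth$snr[kept]
    cw <- sp$width * sp$scale; chh <- sp$height * sp$scale
    crowd <- simulate_crowd(truth_crop, cw, chh, model,
                            n_workers = n_workers, image_id = sp$crop_id,
                            seed = derive_seed(seed, sp$crop_id))
    annos_all[[sp$crop_id]] <- crowd
    if (nrow(crowd) > 0L) {
      qc_args <- config$qc
      qc_args$annos <- crowd
      qc <- do.call(run_qc, qc_args)
      consensus_by_crop[[sp$crop_id]] <- qc$consensus[, c("x", "y")]
    }
  }
  consensus <- reassemble(consensus_by_crop, crops,
                          dedup_radius = dedup_radius)

  # stringency tuning on the matched-filtered image (smoothing at the
  # extracted spot scale suppresses pixel-noise maxima)
  smooth <- gaussian_blur(sim$image,
                          (params$sigma_min + params$sigma_max) / 2)
  tn <- config$tuning
  tune <- tune_stringency(smooth, consensus,
                          grid = tn$grid %||% 0:15,
                          correctness_threshold = threshold,
                          min_distance = tn$min_distance %||% 2)
  peaks <- suppressWarnings(
    local_max_peakfind(smooth, stringency = tune$best_stringency,
                       min_distance = tn$min_distance %||% 2))

  eval_consensus <- match_points(consensus, sim$truth, threshold = threshold)
  eval_detector <- match_points(peaks, sim$truth, threshold = threshold)

  paths <- list(
    config = file.path(config$out_dir, "config.json"),
    truth = file.path(config$out_dir, "truth.csv"),
    annotations = file.path(config$out_dir, "annotations.csv"),
    crop_manifest = file.path(config$out_dir, "crops.csv"),
    consensus = file.path(config$out_dir, "consensus.csv"),
    evaluation = file.path(config$out_dir, "evaluation.json"))
  cfg_plain <- unclass(config)
  jsonlite::write_json(cfg_plain, paths$config, auto_unbox = TRUE, digits = NA,
                       null = "null")
  write_spot_csv(sim$truth, paths$truth)
  write_annotation_csv(do.call(rbind, annos_all), paths$annotations)
  utils::write.csv(manifest_df, paths$crop_manifest, row.names = FALSE)
  cons_out <- cbind(image_id = "img", consensus)
  utils::write.csv(cons_out, paths$consensus, row.names = FALSE)
  jsonlite::write_json(
    list(consensus = list(tp = eval_consensus$tp, fp = eval_consensus$fp,
                          fn = eval_consensus$fn,
                          precision = eval_consensus$precision,
                          recall = eval_consensus$recall,
                          jaccard = eval_consensus$jaccard),
         tuned_detector = list(best_stringency = tune$best_stringency,
                               precision = eval_detector$precision,
                               recall = eval_detector$recall),
         threshold = threshold),
    paths$evaluation, auto_unbox = TRUE, digits = NA)
  if (write_images) {
    paths$image <- file.path(config$out_dir, "image.tif")
    write_image(sim$image, paths$image)
    for (cr in crops) {
      write_image(cr$image,
                  file.path(config$out_dir,
                            paste0("crop_", gsub("\\.", "_", cr$spec$crop_id),
                                   ".png")))
    }
  }
  structure(list(manifest = list(paths = paths, seed = seed,
                                 n_crops = length(crops),
                                 package_version =
                                   as.character(utils::packageVersion("crowdspot"))),
                 truth = sim$truth, crops = manifest_df,
                 consensus = consensus, tuning = tune,
                 evaluation = list(consensus = eval_consensus,
                                   detector = eval_detector)),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  ec <- x$evaluation$consensus
  cat(sprintf("Pipeline run (seed %d): %d truth spots, %d crops, %d consensus points\n",
              x$manifest$seed, nrow(x$truth), x$manifest$n_crops,
              nrow(x$consensus)))
  cat(sprintf("  consensus vs truth: precision %.3f, recall %.3f, Jaccard %.3f\n",
              ec$precision, ec$recall, ec$jaccard))
  cat(sprintf("  tuned peak finder: stringency %d, precision %.3f, recall %.3f\n",
              x$tuning$best_stringency, x$evaluation$detector$precision,
              x$evaluation$detector$recall))
  invisible(x)
}
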