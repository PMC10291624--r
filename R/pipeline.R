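# Declarative augmentation pipeline: a run config lists input clouds, an
# ordered sequence of augmentation specs, and a fixed output size. Every
# randomly drawn parameter is logged to the manifest so any output can be
# re-derived bit-exactly.

AUG_METHODS <- c("downsample", "jitter", "scale", "rotate", "translate",
                 "crop", "brightness", "leaf_translate", "leaf_rotate_z",
                 "leaf_rotate_pca", "crossover")

#' Describe one augmentation method and its parameters
#'
#' @param method one of `downsample`, `jitter`, `scale`, `rotate`,
#'   `translate`, `crop`, `brightness`, `leaf_translate`, `leaf_rotate_z`,
#'   `leaf_rotate_pca`, `crossover`.
#' @param ... method parameters, using the field vocabulary: `sigma`
#'   (jitter), `range` (scale / translate / crop / brightness), `sigma_r`
#'   (rotate), `sigma_l` (leaf_translate), `a` / `b` (leaf rotation
#'   half-widths, degrees), `n_c` (crossover rounds).
#' @param seed optional integer seed for this step.
#' @return an `aug_spec` list.
#' @export
aug_spec <- function(method, ..., seed = NULL) {
  method <- match.arg(method, AUG_METHODS)
  params <- list(...)
  structure(list(method = method, params = params, seed = seed),
            class = "aug_spec")
}

# Apply one spec to one cloud; returns the cloud with a "drawn" attribute.
apply_aug <- function(cloud, spec, n_target) {
  stopifnot(inherits(spec, "aug_spec"))
  p <- spec$params
  s <- spec$seed
  switch(spec$method,
    downsample = downsample_cloud(cloud, p$n_target %||% n_target,
                                  mode = p$mode %||%
                                    (if (is.null(s)) "online" else "offline"),
                                  seed = s),
    jitter = augment_jitter(cloud, p$sigma %||% 0.08, seed = s),
    scale = augment_scale_xy(cloud, p$range %||% c(0.5, 1.5), seed = s),
    rotate = augment_rotate_global(cloud, p$sigma_r %||% 1,
                                   p$gamma_range %||% c(0, 360), seed = s),
    translate = augment_translate_global(cloud, p$range %||% c(-0.05, 0.05),
                                         seed = s),
    crop = augment_crop(cloud, p$range %||% c(0, 0.15),
                        n_target = p$n_target %||% n_target, seed = s),
    brightness = augment_brightness(cloud, p$range %||% c(0.5, 3.0),
                                    seed = s),
    leaf_translate = augment_translate_leaves(cloud, p$sigma_l %||% 0.7,
                                              seed = s),
    leaf_rotate_z = augment_rotate_leaf_z(cloud, gamma = p$gamma,
                                          a = p$a %||% 135, seed = s),
    leaf_rotate_pca = augment_rotate_leaf_pca(cloud, theta = p$theta,
                                              b = p$b %||% 50, seed = s),
    crossover = stop("crossover operates on a plant group, not one cloud"))
}

#' Build a pipeline run configuration
#'
#' @param inputs character vector of input cloud files (PLY/TSV), or a list
#'   of in-memory `plant_cloud`s.
#' @param out_dir output directory (`NULL` to keep results in memory).
#' @param augmentations list of [aug_spec()]s, applied in order after
#'   normalization. An empty list yields normalized, down-sampled copies.
#' @param n_target fixed output point count (default 50000, the standard
#'   network input size).
#' @param seed global integer seed; per-file and per-step seeds derive from
#'   it.
#' @param format output format (see [write_cloud()]).
#' @return a `run_config` list.
#' @export
run_config <- function(inputs, out_dir = NULL, augmentations = list(),
                       n_target = 50000L, seed = 1L, format = "ply") {
  stopifnot_scalar_number(n_target, "n_target", lower = 1)
  structure(list(inputs = inputs, out_dir = out_dir,
                 augmentations = augmentations, n_target = n_target,
                 seed = seed, format = format), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Schema: `inputs` (list of paths), `out_dir`, `n_target`, `seed`,
#' `format`, and `augmentations`, a list of `{method: ..., <params>}`
#' entries using the [aug_spec()] parameter vocabulary (e.g.
#' `method: jitter, sigma: 0.08`; `method: crop, range: [0, 0.15]`).
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  augs <- lapply(y$augmentations %||% list(), function(a) {
    m <- a$method
    a$method <- NULL
    sd <- a$seed
    a$seed <- NULL
    do.call(aug_spec, c(list(method = m), a, list(seed = sd)))
  })
  run_config(inputs = unlist(y$inputs), out_dir = y$out_dir,
             augmentations = augs, n_target = y$n_target %||% 50000L,
             seed = y$seed %||% 1L, format = y$format %||% "ply")
}

#' Run an augmentation pipeline over a set of clouds
#'
#' For each input cloud: normalize (if raw), apply the configured
#' augmentations in order, enforce the fixed output size, and (when
#' `out_dir` is set) write the result. A `crossover` spec, if present, is
#' applied across the whole group (per cultivar) after the per-cloud steps
#' that precede it in the list. Per-file failures are recorded and do not
#' abort the run.
#'
#' The returned manifest holds, per file, every randomly drawn parameter
#' value and the derived seeds, which together re-derive each output
#' bit-exactly.
#'
#' @param config a [run_config()].
#' @return a list with `clouds` (in-memory results), `manifest`
#'   (data.frame: input, output, status, drawn parameter log), and
#'   `n_failed`.
#' @export
run_augment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- config$inputs
  from_files <- is.character(inputs)
  n_in <- length(inputs)
  specs <- config$augmentations
  is_xover <- vapply(specs, function(s) s$method == "crossover", TRUE)
  per_cloud <- specs[!is_xover]
  clouds <- vector("list", n_in)
  logs <- character(n_in)
  status <- rep("ok", n_in)
  names_in <- if (from_files) basename(inputs) else
    sprintf("cloud_%03d", seq_len(n_in))

  for (i in seq_len(n_in)) {
    res <- tryCatch({
      cl <- if (from_files) read_cloud(inputs[[i]]) else inputs[[i]]
      if (!isTRUE(cl$meta$normalized)) cl <- normalize_cloud(cl)
      log_i <- character()
      for (j in seq_along(per_cloud)) {
        spec <- per_cloud[[j]]
        if (is.null(spec$seed)) {
          spec$seed <- child_seed(config$seed, i * 1000L + j)
        }
        cl <- apply_aug(cl, spec, config$n_target)
        drawn <- attr(cl, "drawn")
        if (!is.null(drawn)) {
          log_i <- c(log_i, sprintf("%s[seed=%d](%s)", spec$method,
                                    spec$seed,
                                    paste(names(drawn),
                                          vapply(drawn, function(v)
                                            paste(signif(unlist(v), 6),
                                                  collapse = ";"), ""),
                                          sep = "=", collapse = " ")))
        } else {
          log_i <- c(log_i, sprintf("%s[seed=%d]", spec$method, spec$seed))
        }
      }
      list(cloud = cl, log = paste(log_i, collapse = " | "))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
      logs[i] <- ""
    } else {
      clouds[[i]] <- res$cloud
      logs[i] <- res$log
    }
  }

  ok <- which(status == "ok")
  if (any(is_xover) && length(ok) >= 2L) {
    xspec <- specs[is_xover][[1]]
    xseed <- xspec$seed %||% child_seed(config$seed, 999L)
    groups <- split(ok, vapply(clouds[ok], function(cl) cl$meta$cultivar,
                               ""))
    for (g in groups) {
      if (length(g) < 2L) next
      clouds[g] <- augment_crossover(clouds[g],
                                     n_c = xspec$params$n_c %||% 4L,
                                     n_target = config$n_target,
                                     seed = xseed)
      logs[g] <- paste(logs[g], sprintf("crossover[seed=%d](n_c=%s)", xseed,
                                        xspec$params$n_c %||% 4L),
                       sep = " | ")
    }
  }

  # enforce the fixed-size contract on every surviving cloud
  for (i in ok) {
    if (n_points(clouds[[i]]) != config$n_target) {
      clouds[[i]] <- downsample_cloud(clouds[[i]], config$n_target,
                                      mode = "offline",
                                      seed = child_seed(config$seed,
                                                        500000L + i))
    }
  }

  out_files <- rep(NA_character_, n_in)
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                                recursive = TRUE)
    for (i in ok) {
      ext <- if (config$format == "tsv") ".tsv" else ".ply"
      out_files[i] <- file.path(config$out_dir,
                                paste0(sub("\\.[^.]*$", "", names_in[i]),
                                       "_aug", ext))
      write_cloud(clouds[[i]], out_files[i], format = config$format)
    }
  }
  manifest <- data.frame(input = names_in, output = out_files,
                         status = status, log = logs,
                         stringsAsFactors = FALSE)
  if (!is.null(config$out_dir)) {
    data.table::fwrite(manifest, file.path(config$out_dir,
                                           "augment_manifest.tsv"),
                       sep = "\t")
  }
  list(clouds = clouds, manifest = manifest,
       n_failed = sum(status != "ok"))
}
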