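# Readers and writers for the community prediction/label CSV dialect:
# a 3-row header (scorer / bodyparts / coords) with x, y[, likelihood]
# columns per bodypart and the frame index in the first column. One file
# per camera; the ensemble member index is encoded in the filename
# (<view>_member<m>.csv).

#' Read one prediction CSV
#'
#' @param path Path to a CSV in the scorer/bodyparts/coords dialect. A
#'   missing `likelihood` column is accepted (`likelihood` is `NULL` then).
#' @return List with `coords` (`[T, K, 2]`), `likelihood` (`[T, K]` or
#'   `NULL`), `extra` (named list of further per-keypoint columns, e.g.
#'   `var_x`), `keypoints`, `frames` (integer vector), `scorer`.
#' @export
read_predictions_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  if (length(hdr) < 3) stop(sprintf("%s: missing 3-row header", path))
  h <- lapply(hdr, function(x) strsplit(x, ",", fixed = TRUE)[[1]])
  labels <- vapply(h, `[[`, "", 1)
  if (!identical(tolower(labels), c("scorer", "bodyparts", "coords")))
    stop(sprintf("%s: malformed header (expected scorer/bodyparts/coords rows, got %s)",
                 path, paste(labels, collapse = "/")))
  scorer <- h[[1]][2]
  bodyparts <- h[[2]][-1]
  coords_row <- h[[3]][-1]
  if (length(bodyparts) != length(coords_row))
    stop(sprintf("%s: header rows have inconsistent lengths", path))
  dat <- utils::read.csv(path, skip = 3, header = FALSE)
  frames <- as.integer(dat[[1]])
  vals <- as.matrix(dat[, -1, drop = FALSE])
  if (ncol(vals) != length(bodyparts))
    stop(sprintf("%s: data columns do not match header", path))
  keypoints <- unique(bodyparts)
  T_ <- nrow(vals); K <- length(keypoints)
  coords <- array(NA_real_, c(T_, K, 2))
  likelihood <- NULL
  extra <- list()
  for (k in seq_len(K)) {
    cols <- which(bodyparts == keypoints[k])
    for (j in cols) {
      cname <- coords_row[j]
      if (cname == "x") coords[, k, 1] <- vals[, j]
      else if (cname == "y") coords[, k, 2] <- vals[, j]
      else if (cname == "likelihood") {
        if (is.null(likelihood)) likelihood <- matrix(NA_real_, T_, K)
        likelihood[, k] <- vals[, j]
      } else {
        if (is.null(extra[[cname]])) extra[[cname]] <- matrix(NA_real_, T_, K)
        extra[[cname]][, k] <- vals[, j]
      }
    }
  }
  list(coords = coords, likelihood = likelihood, extra = extra,
       keypoints = keypoints, frames = frames, scorer = scorer)
}

# Shared writer for the 3-row-header dialect.
write_dialect_csv <- function(path, blocks, keypoints, frames, scorer) {
  coord_names <- names(blocks)
  K <- length(keypoints)
  hdr1 <- c("scorer", rep(scorer, K * length(coord_names)))
  hdr2 <- c("bodyparts", rep(keypoints, each = length(coord_names)))
  hdr3 <- c("coords", rep(coord_names, K))
  body <- matrix(NA_real_, length(frames), K * length(coord_names))
  for (k in seq_len(K)) {
    for (j in seq_along(coord_names)) {
      body[, (k - 1) * length(coord_names) + j] <- blocks[[j]][, k]
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(hdr1, collapse = ","),
               paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), con)
  body_chr <- apply(body, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = ","))
  writeLines(paste(frames, body_chr, sep = ","), con)
  invisible(path)
}

#' Write one prediction CSV
#'
#' Emits the scorer/bodyparts/coords dialect with `x`, `y` and optional
#' `likelihood` columns per bodypart.
#'
#' @param path Output path.
#' @param coords Numeric array `[T, K, 2]`.
#' @param likelihood Optional `[T, K]` matrix.
#' @param keypoints Character vector of bodypart names.
#' @param frames Integer frame indices (default `0:(T-1)`).
#' @param scorer Scorer name (default `"mveks"`).
#' @param extra Optional named list of further `[T, K]` column blocks
#'   (e.g. `var_x`, `var_y`), appended after likelihood.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(path, coords, likelihood = NULL,
                                  keypoints = NULL, frames = NULL,
                                  scorer = "mveks", extra = NULL) {
  d <- dim(coords)
  stopifnot(length(d) == 3, d[3] == 2)
  if (is.null(keypoints)) keypoints <- paste0("kp", seq_len(d[2]))
  if (is.null(frames)) frames <- seq_len(d[1]) - 1L
  blocks <- list(x = matrix(coords[, , 1], d[1], d[2]),
                 y = matrix(coords[, , 2], d[1], d[2]))
  if (!is.null(likelihood)) blocks$likelihood <- likelihood
  if (!is.null(extra)) blocks <- c(blocks, extra)
  write_dialect_csv(path, blocks, keypoints, frames, scorer)
}

#' Write one label CSV (x and y columns only)
#'
#' @inheritParams write_predictions_csv
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(path, coords, keypoints = NULL, frames = NULL,
                             scorer = "mveks") {
  write_predictions_csv(path, coords, likelihood = NULL,
                        keypoints = keypoints, frames = frames,
                        scorer = scorer)
}

#' Read an ensemble of per-view, per-member prediction files
#'
#' @param paths A list of length `V` (named by view), each element a
#'   character vector of per-member file paths (same member order across
#'   views). All files must share the same bodypart set and frame count;
#'   keypoint order is taken from the first file, files with permuted
#'   bodypart columns are handled by name.
#' @return An [ensemble_predictions()].
#' @export
read_predictions <- function(paths) {
  V <- length(paths)
  stopifnot(V >= 2)
  M <- length(paths[[1]])
  views <- names(paths)
  if (is.null(views)) views <- paste0("view", seq_len(V))
  first <- read_predictions_csv(paths[[1]][1])
  keypoints <- first$keypoints
  T_ <- length(first$frames)
  K <- length(keypoints)
  coords <- array(NA_real_, c(M, T_, V, K, 2))
  lik <- array(NA_real_, c(M, T_, V, K))
  have_lik <- TRUE
  bad <- character(0)
  for (v in seq_len(V)) {
    if (length(paths[[v]]) != M)
      stop("all views must have the same number of member files")
    for (m in seq_len(M)) {
      p <- read_predictions_csv(paths[[v]][m])
      if (!setequal(p$keypoints, keypoints) || length(p$frames) != T_) {
        bad <- c(bad, paths[[v]][m])
        next
      }
      reord <- match(keypoints, p$keypoints)
      coords[m, , v, , ] <- p$coords[, reord, , drop = FALSE]
      if (is.null(p$likelihood)) have_lik <- FALSE
      else lik[m, , v, ] <- p$likelihood[, reord, drop = FALSE]
    }
  }
  if (length(bad))
    stop(sprintf("inconsistent bodyparts or frame count in: %s",
                 paste(bad, collapse = ", ")))
  ensemble_predictions(coords, likelihood = if (have_lik) lik else NULL,
                       keypoints = keypoints, views = views)
}

#' Write smoothed outputs, one CSV per view
#'
#' Columns per bodypart: `x`, `y`, `likelihood`, `var_x`, `var_y`.
#' `var_x`/`var_y` are the posterior predictive variances (pixels^2);
#' `likelihood` is the bounded confidence proxy
#' `1 / (1 + sqrt(var_x + var_y))` so that readers of the plain dialect that
#' ignore extra columns still see a monotone confidence in `(0, 1]`.
#'
#' @param result An `eks_result` from [smooth_all_keypoints()].
#' @param dir Output directory (created if missing).
#' @param scorer Scorer name (default `"mveks"`).
#' @return Named character vector of file paths, invisibly.
#' @export
write_smoothed <- function(result, dir, scorer = "mveks") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(result$means)
  T_ <- d[1]; V <- d[2]; K <- d[3]
  paths <- character(V)
  for (v in seq_len(V)) {
    coords <- array(result$means[, v, , ], c(T_, K, 2))
    var_x <- matrix(result$cov[, v, , 1, 1], T_, K)
    var_y <- matrix(result$cov[, v, , 2, 2], T_, K)
    lik <- 1 / (1 + sqrt(var_x + var_y))
    path <- file.path(dir, sprintf("%s_smoothed.csv", result$views[v]))
    write_predictions_csv(path, coords, likelihood = lik,
                          keypoints = result$keypoints,
                          scorer = scorer,
                          extra = list(var_x = var_x, var_y = var_y))
    paths[v] <- path
  }
  names(paths) <- result$views
  invisible(paths)
}

# Known run-configuration keys and their defaults.
run_config_defaults <- function() {
  list(mode = "linear", latent_dim = 3, s = "auto",
       inflate = FALSE, inflate_threshold = 5, inflate_factor = 10,
       inflate_max_rounds = 25, keep_fraction = 0.6, k = 3000,
       seed = 1, calib = NULL, input_dir = NULL, output_dir = NULL)
}

#' Read a run configuration file
#'
#' A flat YAML file of key-value pairs; unknown keys are rejected with a
#' message naming them. Missing keys take the documented defaults.
#'
#' @param path Path to the YAML file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration keys: %s (known keys: %s)",
                 paste(unknown, collapse = ", "),
                 paste(names(defaults), collapse = ", ")))
  utils::modifyList(defaults, cfg)
}

#' Write a run configuration file
#'
#' @param config Named list (validated against the known keys).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), names(run_config_defaults()))
  if (length(unknown))
    stop(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")))
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}
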