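#' Read a multi-camera calibration file
#'
#' The calibration format is a TOML file with one table per camera:
#'
#' ```toml
#' [cam_0]
#' name = "cam_0"
#' size = [400, 400]
#' matrix = [[1000.0, 0.0, 200.0], [0.0, 1000.0, 200.0], [0.0, 0.0, 1.0]]
#' distortions = [-0.1, 0.02, 0.001, -0.001, 0.0]
#' rotation = [0.0, 1.2, 0.0]
#' translation = [0.0, 0.0, 3.0]
#' ```
#'
#' `matrix` is the row-major 3x3 intrinsic matrix, `distortions` the five
#' coefficients in the order `k1 k2 p1 p2 k3`, `rotation` an axis-angle
#' world-to-camera rotation and `translation` the world-to-camera offset.
#' Unknown keys are tolerated and ignored; table order defines view order.
#'
#' @param path Path to the calibration file.
#' @return A [camera_rig()].
#' @export
read_calibration <- function(path) {
  tabs <- parse_toml(path)
  if (length(tabs) < 2) stop("calibration file must define at least 2 cameras")
  cams <- lapply(names(tabs), function(nm) {
    tab <- tabs[[nm]]
    for (key in c("matrix", "distortions", "rotation", "translation")) {
      if (is.null(tab[[key]]))
        stop(sprintf("camera table '%s' is missing key '%s'", nm, key))
    }
    Km <- tab$matrix
    if (!is.matrix(Km)) Km <- matrix(as.numeric(unlist(Km)), 3, 3, byrow = TRUE)
    if (!all(dim(Km) == c(3, 3)))
      stop(sprintf("camera table '%s': 'matrix' must be 3x3", nm))
    camera_model(
      name = if (!is.null(tab$name)) tab$name else nm,
      focal = c(Km[1, 1], Km[2, 2]),
      principal = c(Km[1, 3], Km[2, 3]),
      distortion = as.numeric(tab$distortions),
      rotation = as.numeric(tab$rotation),
      translation = as.numeric(tab$translation),
      size = if (!is.null(tab$size)) as.numeric(tab$size) else NULL
    )
  })
  camera_rig(cams)
}

#' Write a camera rig to a calibration file
#'
#' Emits the TOML dialect documented in [read_calibration()].
#'
#' @param rig A [camera_rig()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(rig, path) {
  fmt_num <- function(x) {
    s <- vapply(x, function(v) formatC(v, format = "g", digits = 17), "")
    ifelse(grepl("[.e]", s), s, paste0(s, ".0"))
  }
  fmt_arr <- function(x) paste0("[", paste(fmt_num(x), collapse = ", "), "]")
  lines <- character(0)
  for (cam in rig$cameras) {
    Km <- rbind(c(cam$focal[1], 0, cam$principal[1]),
                c(0, cam$focal[2], cam$principal[2]),
                c(0, 0, 1))
    rows <- apply(Km, 1, fmt_arr)
    lines <- c(lines,
      sprintf("[%s]", cam$name),
      sprintf('name = "%s"', cam$name),
      if (!is.null(cam$size)) sprintf("size = %s", fmt_arr(cam$size)),
      sprintf("matrix = [%s]", paste(rows, collapse = ", ")),
      sprintf("distortions = %s", fmt_arr(cam$distortion)),
      sprintf("rotation = %s", fmt_arr(cam$rotation)),
      sprintf("translation = %s", fmt_arr(cam$translation)),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

# Minimal TOML subset parser: [table] headers; key = value lines where value
# is a double-quoted string, a number, or a (possibly nested) numeric array.
# Comments (#) and blank lines skipped; extra keys kept as-is.
parse_toml <- function(path) {
  if (!file.exists(path)) stop(sprintf("calibration file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  # strip comments outside strings (values here never contain '#')
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  # join lines so multi-line arrays close their brackets
  out <- list()
  current <- NULL
  i <- 1
  n <- length(raw)
  while (i <= n) {
    line <- raw[i]
    i <- i + 1
    if (line == "") next
    if (grepl("^\\[[^]]+\\]$", line)) {
      current <- gsub("^\\[|\\]$", "", line)
      out[[current]] <- list()
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(m) == 0) stop(sprintf("cannot parse calibration line: '%s'", line))
    key <- m[2]
    val <- m[3]
    # pull in continuation lines until brackets balance
    while (unbalanced_brackets(val) && i <= n) {
      val <- paste(val, raw[i])
      i <- i + 1
    }
    if (is.null(current)) stop("calibration values must appear inside a [table]")
    out[[current]][[key]] <- parse_toml_value(trimws(val))
  }
  out
}

unbalanced_brackets <- function(s) {
  chars <- strsplit(s, "")[[1]]
  sum(chars == "[") > sum(chars == "]")
}

parse_toml_value <- function(val) {
  if (grepl('^".*"$', val)) return(gsub('^"|"$', "", val))
  if (grepl("^\\[", val)) return(parse_toml_array(val))
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) {
    if (val %in% c("true", "false")) return(val == "true")
    stop(sprintf("unsupported calibration value: '%s'", val))
  }
  num
}

# Recursive numeric array parser. Nested arrays of equal length become a
# row-major matrix (list of rows -> rbind).
parse_toml_array <- function(val) {
  inner <- sub("^\\[", "", sub("\\]$", "", val))
  if (grepl("^\\s*\\[", inner)) {
    # split top-level elements, each itself an array
    parts <- split_top_level(inner)
    rows <- lapply(parts, parse_toml_array)
    if (length(unique(vapply(rows, length, 1L))) == 1)
      return(do.call(rbind, rows))
    return(rows)
  }
  if (trimws(inner) == "") return(numeric(0))
  as.numeric(strsplit(inner, ",")[[1]])
}

split_top_level <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0
  buf <- character(0)
  parts <- character(0)
  for (ch in chars) {
    if (ch == "[") depth <- depth + 1
    if (ch == "]") depth <- depth - 1
    if (ch == "," && depth == 0) {
      parts <- c(parts, paste(buf, collapse = ""))
      buf <- character(0)
    } else buf <- c(buf, ch)
  }
  if (length(buf)) parts <- c(parts, paste(buf, collapse = ""))
  parts <- trimws(parts)
  parts[nzchar(parts)]
}
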