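# RELION-style STAR I/O. The writer emits the RELION 3.1+ optics-group
# dialect (data_optics + data_particles, shifts in Angstrom via
# rlnOriginXAngst/YAngst); the reader accepts that dialect and falls back
# to flat single-table files with per-row CTF columns and pixel shifts.

#' Parse a STAR file into tables
#'
#' Generic parser: every `data_<name>` block becomes a data.frame (loop_
#' blocks row-wise, key-value blocks as a single row). Numeric columns are
#' converted automatically.
#'
#' @param path Path to a STAR file.
#' @return Named list of data.frames.
#' @export
read_star <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!startsWith(lines[i], "data_")) { i <- i + 1L; next }
    block <- substring(lines[i], 6L)
    if (block == "") block <- "root"
    i <- i + 1L
    while (i <= n && lines[i] == "") i <- i + 1L
    if (i <= n && lines[i] == "loop_") {
      i <- i + 1L
      cols <- character()
      while (i <= n && startsWith(lines[i], "_")) {
        cols <- c(cols, sub("^_", "", strsplit(lines[i], "\\s+")[[1]][1]))
        i <- i + 1L
      }
      rows <- list()
      while (i <= n && lines[i] != "" && !startsWith(lines[i], "data_")) {
        rows[[length(rows) + 1L]] <- strsplit(lines[i], "\\s+")[[1]]
        i <- i + 1L
      }
      if (length(rows)) {
        bad <- vapply(rows, length, 1L) != length(cols)
        if (any(bad)) stop("STAR row/column count mismatch in data_", block)
        df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
      } else {
        df <- as.data.frame(matrix(character(), 0, length(cols)),
                            stringsAsFactors = FALSE)
      }
      names(df) <- cols
    } else {
      keys <- character(); vals <- character()
      while (i <= n && (startsWith(lines[i], "_") || lines[i] == "")) {
        if (startsWith(lines[i], "_")) {
          kv <- strsplit(lines[i], "\\s+")[[1]]
          keys <- c(keys, sub("^_", "", kv[1]))
          vals <- c(vals, if (length(kv) > 1) kv[2] else NA_character_)
        }
        i <- i + 1L
        if (i <= n && startsWith(lines[i], "data_")) break
      }
      df <- as.data.frame(as.list(vals), stringsAsFactors = FALSE)
      names(df) <- keys
    }
    for (cn in names(df)) {
      suppress <- suppressWarnings(as.numeric(df[[cn]]))
      if (nrow(df) == 0 || !anyNA(suppress)) df[[cn]] <- suppress
    }
    out[[block]] <- df
  }
  if (!length(out)) stop("no data_ block found in ", path)
  out
}

#' Write tables as a STAR file
#'
#' @param tables Named list of data.frames; each becomes a `data_<name>`
#'   loop_ block with deterministic column order (as given).
#' @param path Output path.
#' @export
write_star <- function(tables, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# version 30001", con)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    writeLines(c("", paste0("data_", nm), "", "loop_"), con)
    writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
    if (nrow(df)) {
      cells <- vapply(df, function(col) {
        if (is.numeric(col)) sprintf("%.6f", col) else as.character(col)
      }, character(nrow(df)))
      if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
      writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' One particle's metadata
#'
#' @param image_index 1-based index into the associated image stack.
#' @param euler Euler angles `(rot, tilt, psi)` in degrees (ZYZ, see
#'   [rotation_matrix()]).
#' @param shift In-plane shift `(sx, sy)` in pixels.
#' @param ctf A [ctf_params()] object.
#' @return An object of class `particle_record`.
#' @export
particle_record <- function(image_index, euler, shift, ctf) {
  euler <- as.numeric(euler); shift <- as.numeric(shift)
  stopifnot(length(euler) == 3L, length(shift) == 2L,
            inherits(ctf, "ctf_params"))
  if (!all(is.finite(euler)) || !all(is.finite(shift)))
    stop("non-finite pose parameters")
  if (euler[2] < 0 || euler[2] > 180)
    stop("tilt must lie in [0, 180] degrees")
  structure(list(image_index = as.integer(image_index), euler = euler,
                 shift = shift, ctf = ctf),
            class = "particle_record")
}

star_required <- c("rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi",
                   "rlnDefocusU", "rlnDefocusV")

#' Read a particle dataset (STAR metadata + MRC stack)
#'
#' Accepts RELION 3.1 optics-group files (`data_optics` +
#' `data_particles`, shifts in Angstrom) as well as flat tables with
#' per-row voltage/Cs/amplitude-contrast columns and pixel shifts
#' (`rlnOriginX/Y`). Angstrom shifts are converted to pixels using the
#' pixel size.
#'
#' @param star_path Path to the STAR file.
#' @param stack_path Path to the MRC stack referenced by the metadata.
#' @return List with elements `stack` ([image_stack()]) and `records`
#'   (list of [particle_record()], in file order).
#' @export
read_particles <- function(star_path, stack_path) {
  tabs <- read_star(star_path)
  part <- if ("particles" %in% names(tabs)) tabs$particles else tabs[[length(tabs)]]
  optics <- tabs[["optics"]]
  miss <- setdiff(star_required, names(part))
  if (length(miss))
    stop("STAR file lacks mandatory columns: ", paste(miss, collapse = ", "))
  getcol <- function(nm, default = NULL) {
    if (nm %in% names(part)) part[[nm]]
    else if (!is.null(optics) && nm %in% names(optics))
      rep(optics[[nm]][1], nrow(part))
    else if (!is.null(default)) rep(default, nrow(part))
    else stop("STAR file lacks mandatory column ", nm)
  }
  pixel <- getcol("rlnImagePixelSize", default = NA)
  if (all(is.na(pixel))) pixel <- getcol("rlnDetectorPixelSize")
  voltage <- getcol("rlnVoltage")
  cs <- getcol("rlnSphericalAberration")
  ac <- getcol("rlnAmplitudeContrast")
  stack <- read_stack(stack_path)
  if (stack$n != nrow(part))
    stop("row count (", nrow(part), ") does not match stack size (",
         stack$n, ")")
  if ("rlnOriginXAngst" %in% names(part)) {
    sx <- part$rlnOriginXAngst / pixel
    sy <- part$rlnOriginYAngst / pixel
  } else if ("rlnOriginX" %in% names(part)) {
    sx <- part$rlnOriginX
    sy <- part$rlnOriginY
  } else {
    sx <- sy <- rep(0, nrow(part))
  }
  astig <- if ("rlnDefocusAngle" %in% names(part)) part$rlnDefocusAngle
           else rep(0, nrow(part))
  idx <- if ("rlnImageName" %in% names(part))
    as.integer(sub("@.*$", "", part$rlnImageName)) else seq_len(nrow(part))
  records <- lapply(seq_len(nrow(part)), function(i) {
    particle_record(
      image_index = idx[i],
      euler = c(part$rlnAngleRot[i], part$rlnAngleTilt[i], part$rlnAnglePsi[i]),
      shift = c(sx[i], sy[i]),
      ctf = ctf_params(defocus_u = part$rlnDefocusU[i],
                       defocus_v = part$rlnDefocusV[i],
                       astig_angle = astig[i], voltage = voltage[i],
                       cs = cs[i], amplitude_contrast = ac[i],
                       pixel_size = pixel[i]))
  })
  list(stack = stack, records = records)
}

#' Write a particle dataset (STAR metadata + MRC stack)
#'
#' Inverse of [read_particles()]; writes the RELION 3.1 optics-group
#' dialect with shifts in Angstrom. Microscope parameters for the optics
#' table are taken from the first record (one optics group).
#'
#' @param stack An [image_stack()].
#' @param records List of [particle_record()] (may be empty).
#' @param star_path,stack_path Output paths.
#' @export
write_particles <- function(stack, records, star_path, stack_path) {
  stopifnot(inherits(stack, "image_stack"))
  write_stack(stack, stack_path)
  px <- stack$pixel_size
  if (length(records)) {
    ctf0 <- records[[1]]$ctf
    optics <- data.frame(
      rlnOpticsGroup = 1, rlnVoltage = ctf0$voltage,
      rlnSphericalAberration = ctf0$cs,
      rlnAmplitudeContrast = ctf0$amplitude_contrast,
      rlnImagePixelSize = px, rlnImageSize = stack$box)
    g <- function(f) vapply(records, f, numeric(1))
    particles <- data.frame(
      rlnImageName = sprintf("%06d@%s", g(function(r) r$image_index),
                             basename(stack_path)),
      rlnAngleRot = g(function(r) r$euler[1]),
      rlnAngleTilt = g(function(r) r$euler[2]),
      rlnAnglePsi = g(function(r) r$euler[3]),
      rlnOriginXAngst = g(function(r) r$shift[1]) * px,
      rlnOriginYAngst = g(function(r) r$shift[2]) * px,
      rlnDefocusU = g(function(r) r$ctf$defocus_u),
      rlnDefocusV = g(function(r) r$ctf$defocus_v),
      rlnDefocusAngle = g(function(r) r$ctf$astig_angle),
      rlnOpticsGroup = 1)
  } else {
    optics <- data.frame(
      rlnOpticsGroup = 1, rlnVoltage = 300, rlnSphericalAberration = 2.7,
      rlnAmplitudeContrast = 0.1, rlnImagePixelSize = px,
      rlnImageSize = stack$box)
    particles <- data.frame(
      rlnImageName = character(), rlnAngleRot = numeric(),
      rlnAngleTilt = numeric(), rlnAnglePsi = numeric(),
      rlnOriginXAngst = numeric(), rlnOriginYAngst = numeric(),
      rlnDefocusU = numeric(), rlnDefocusV = numeric(),
      rlnDefocusAngle = numeric(), rlnOpticsGroup = numeric())
  }
  write_star(list(optics = optics, particles = particles), star_path)
  invisible(star_path)
}
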