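## Plain-text containers: morphology (YAML header + digit-grid layers),
## production CSV, legacy VTK STRUCTURED_POINTS snapshots.
## Indexing in files is 0-based (row, col[, layer]), row-major.

#' Write a lobule morphology to a plain-text container
#'
#' Format: a YAML header (grid shape, cell geometry, seed, recipe, layer
#' kinds, 0-based inlet/outlet cell lists) terminated by a `---` line,
#' followed by one block of label digits per layer (one row per line,
#' characters 0/1/2 per [lobule_labels()]), blocks separated by blank lines.
#'
#' @param m A lobule morphology.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_morphology <- function(m, path) {
  stopifnot(inherits(m, "lobule"))
  dims <- dim(m$labels)
  if (length(dims) == 2L) dims <- c(dims, 1L)
  cells0 <- function(cells) {
    apply(unname(as.matrix(cells)) - 1L, 1, as.list)
  }
  hdr <- list(
    format = "lobulesim-morphology-v1",
    dims = as.integer(dims),
    cell_size_um = m$cell_size_um,
    layer_thickness_um = rep(m$layer_thickness_um, length.out = dims[3]),
    layer_kind = m$layer_kind %||% rep("DLA", dims[3]),
    seed = if (is.na(m$seed)) NULL else m$seed,
    inlet_cells = cells0(m$inlet_cells),
    outlet_cells = lapply(m$outlet_cells, cells0)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(yaml::as.yaml(hdr), con)
  writeLines("---", con)
  lab <- array(m$labels, dims)
  for (z in seq_len(dims[3])) {
    block <- apply(lab[, , z], 1, paste0, collapse = "")
    writeLines(block, con)
    if (z < dims[3]) writeLines("", con)
  }
  invisible(path)
}

#' Read a lobule morphology from a plain-text container
#'
#' @param path File written by [write_morphology()].
#' @return A `"lobule"` object.
#' @export
read_morphology <- function(path) {
  lines <- readLines(path)
  sep <- which(lines == "---")[1]
  if (is.na(sep)) stop("not a morphology container: missing '---' separator",
                       call. = FALSE)
  hdr <- yaml::yaml.load(paste(lines[seq_len(sep - 1L)], collapse = "\n"))
  if (!identical(hdr$format, "lobulesim-morphology-v1")) {
    stop("unrecognized morphology format", call. = FALSE)
  }
  dims <- as.integer(unlist(hdr$dims))
  body <- lines[-seq_len(sep)]
  body <- body[nzchar(body)]
  if (length(body) != dims[1] * dims[3]) {
    stop("label block size does not match header dims", call. = FALSE)
  }
  lab <- array(0L, dims)
  for (z in seq_len(dims[3])) {
    rows <- body[(z - 1L) * dims[1] + seq_len(dims[1])]
    lab[, , z] <- t(vapply(strsplit(rows, ""),
                           function(ch) as.integer(ch), integer(dims[2])))
  }
  cells1 <- function(lst) {
    do.call(rbind, lapply(lst, function(p) as.integer(unlist(p)) + 1L))
  }
  inlet <- cells1(hdr$inlet_cells)
  outlets <- lapply(hdr$outlet_cells, cells1)
  if (dims[3] == 1L) {
    lab <- lab[, , 1]
    if (ncol(inlet) == 3L) inlet <- inlet[, 1:2, drop = FALSE]
    outlets <- lapply(outlets, function(o)
      if (ncol(o) == 3L) o[, 1:2, drop = FALSE] else o)
  }
  m <- lobule_morphology(lab, inlet, outlets,
                         cell_size_um = hdr$cell_size_um,
                         layer_thickness_um = unlist(hdr$layer_thickness_um))
  m$layer_kind <- unlist(hdr$layer_kind)
  m$seed <- as.integer(hdr$seed %||% NA_integer_)
  m
}

#' Import a binary sinusoid mask as a 2D morphology
#'
#' Converts an image-derived logical mask (`TRUE` = sinusoid) into a lobule:
#' the bounding hexagon is applied, masked cells become sinusoid, the
#' standard centre/corner port blocks are stamped and connectivity repaired.
#'
#' @param mask Logical (or 0/1) square matrix.
#' @param cell_size_um Lateral cell size, um.
#' @return A `"lobule_2d"` object.
#' @export
morphology_from_mask <- function(mask, cell_size_um = 6) {
  mask <- as.matrix(mask) != 0
  M <- nrow(mask)
  if (ncol(mask) != M) stop("mask must be square", call. = FALSE)
  hexm <- hex_mask(M)
  labels <- matrix(.LBL[["OUTSIDE"]], M, M)
  labels[hexm] <- .LBL[["TISSUE"]]
  labels[hexm & mask] <- .LBL[["SINUSOID"]]
  ctr <- rep(as.integer(ceiling(M / 2)), 2)
  corners <- hex_corner_cells(M)
  inlet <- port_block(ctr, hexm)
  outlets <- lapply(1:6, function(k) port_block(corners[k, ], hexm))
  names(outlets) <- LETTERS[1:6]
  for (cells in c(list(inlet), outlets)) labels[cells] <- .LBL[["SINUSOID"]]
  rep <- repair_connectivity_cpp(labels, inlet - 1L)
  m <- lobule_morphology(rep$labels, inlet, outlets,
                         cell_size_um = cell_size_um,
                         layer_thickness_um = cell_size_um)
  m$n_bridged <- rep$n_bridged
  m
}

#' Write production curves to CSV
#'
#' Long format with columns `time_min, port, species, outflow_rate_cm3_min,
#' mole_fraction, cumulative` (cumulative production in mole fraction cm^3).
#'
#' @param rec A [run_infusion()] record.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_production_csv <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.production_record <- function(x, ...) {
  ports <- dimnames(x$conc)[[2]]
  nt <- length(x$time_min)
  if (nt == 0L) {
    return(data.frame(time_min = numeric(), port = character(),
                      species = character(),
                      outflow_rate_cm3_min = numeric(),
                      mole_fraction = numeric(), cumulative = numeric()))
  }
  grid <- expand.grid(t = seq_len(nt), p = seq_along(ports),
                      s = seq_along(x$species))
  data.frame(
    time_min = x$time_min[grid$t],
    port = ports[grid$p],
    species = x$species[grid$s],
    outflow_rate_cm3_min = unname(x$port_rates_cm3_min[grid$p]),
    mole_fraction = x$conc[cbind(grid$t, grid$p, grid$s)],
    cumulative = x$cumulative[cbind(grid$t, grid$p, grid$s)]
  )
}

#' Read a production CSV
#'
#' @param path CSV written by [write_production_csv()].
#' @return Data frame with the production columns, numerically validated.
#' @export
read_production_csv <- function(path) {
  need <- c("time_min", "port", "species", "outflow_rate_cm3_min",
            "mole_fraction", "cumulative")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(need %in% names(df))) {
    stop("malformed production file (line 1): expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (col in c("time_min", "outflow_rate_cm3_min", "mole_fraction",
                "cumulative")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("malformed production file (line %d): '%s' is not numeric in column %s",
                     bad[1] + 1L, v[bad[1]], col), call. = FALSE)
      }
      df[[col]] <- vn
    }
  }
  df[need]
}

#' Write a field snapshot as legacy VTK STRUCTURED_POINTS
#'
#' ASCII legacy VTK with per-axis spacing equal to the lateral cell size;
#' non-uniform layer thicknesses are handled by resampling each layer into
#' an integer number of slices of the finest spacing (6 um DLA / 12 um
#' tissue layers give 1 and 2 slices).
#'
#' @param field Numeric array on the morphology grid (2D matrix or 3D
#'   array); `NA` is written as 0.
#' @param m The lobule morphology providing the geometry.
#' @param path Output `.vtk` path.
#' @param name Scalar field name in the file.
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(field, m, path, name = "field") {
  stopifnot(inherits(m, "lobule"))
  dims <- dim(m$labels)
  if (length(dims) == 2L) dims <- c(dims, 1L)
  field <- array(field, dims)
  thick <- rep(m$layer_thickness_um, length.out = dims[3])
  dz <- min(thick)
  repz <- as.integer(round(thick / dz))
  if (max(abs(thick / dz - repz)) > 1e-9) {
    stop("layer thicknesses must be integer multiples of the finest spacing",
         call. = FALSE)
  }
  zmap <- rep(seq_len(dims[3]), repz)
  nx <- dims[2]; ny <- dims[1]; nz <- length(zmap)
  h <- m$cell_size_um
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("lobulesim snapshot:", name),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", nx, ny, nz),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", h, h, dz),
               sprintf("POINT_DATA %d", nx * ny * nz),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  vals <- field[, , zmap, drop = FALSE]
  vals[is.na(vals)] <- 0
  ## VTK is x-fastest: x = column, y = row, z = slice
  out <- aperm(vals, c(2, 1, 3))
  writeLines(formatC(as.vector(out), format = "g", digits = 7), con)
  invisible(path)
}
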