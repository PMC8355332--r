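## Readers and writers for the plain-text formats shared across modules:
## two-column force-curve text, single-channel TIFF, track CSV, GRO and
## multi-frame XYZ coordinates, topology/LJ CSV tables, and ground-truth
## JSON sidecars.  Every writer emits exactly what the paired reader
## consumes (round-trip within format precision).

#' Read an AFM force curve from two-column whitespace text
#'
#' Expects two numeric columns (z in nm, force in nN); lines starting with
#' `#` are comments.  Rows are ordered by ascending z.
#'
#' @param path file path.
#' @param tip_radius,poisson,spring_constant probe metadata to attach
#'   (defaults 10 nm, 0.4, 0.02 N/m).
#' @return a [force_curve].
#' @export
parse_force_curve_file <- function(path, tip_radius = 10, poisson = 0.4,
                                   spring_constant = 0.02) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep))
    stop(sprintf("%s: no data rows (only comments or blank lines)", path),
         call. = FALSE)
  rows <- which(keep)
  parsed <- lapply(rows, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) != 2)
      stop(sprintf("%s: line %d: expected 2 columns, found %d",
                   path, i, length(fields)), call. = FALSE)
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("%s: line %d: non-numeric value", path, i), call. = FALSE)
    vals
  })
  m <- do.call(rbind, parsed)
  o <- order(m[, 1])
  force_curve(z = m[o, 1], force = m[o, 2], tip_radius = tip_radius,
              poisson = poisson, spring_constant = spring_constant)
}

#' Write a force curve as two-column whitespace text
#'
#' @param curve a [force_curve].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  header <- c("# AFM approach force curve",
              "# columns: z_nm force_nN",
              sprintf("# tip_radius_nm %g  poisson %g  spring_constant_N_per_m %g",
                      curve$tip_radius, curve$poisson, curve$spring_constant))
  body <- sprintf("%.10g %.10g", curve$z, curve$force)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a single-channel TIFF image
#'
#' @param path TIFF path.
#' @return numeric matrix in `[0, 1]` (rows = y, columns = x).
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] != 1)
      stop("expected a single-channel image", call. = FALSE)
    img <- img[, , 1]
  }
  img
}

#' Write a single-channel image as 16-bit TIFF
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  img <- .as_image_matrix(image)
  tiff::writeTIFF(pmin(pmax(img, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read single-cell tracks from CSV
#'
#' @param path CSV with header `cell_id,t_min,x_um,y_um`.
#' @return a [track_set].
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path)
  track_set(df)
}

#' Write single-cell tracks to CSV
#'
#' @param tracks a [track_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks)[c("cell_id", "t_min", "x_um", "y_um")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' Fixed-column Gromacs GRO layout: title, atom count, atom records
#' (positions in nm, 3 decimals), final box line.  Only cubic boxes are
#' supported.
#'
#' @param path GRO path.
#' @return list with `frame` (a [bead_frame]), `atom_names`, `res_names`.
#' @export
parse_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop(sprintf("%s: truncated GRO file", path), call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n))
    stop(sprintf("%s: line 2: invalid atom count", path), call. = FALSE)
  if (length(lines) < n + 3)
    stop(sprintf("%s: expected %d atom lines plus a box line", path, n),
         call. = FALSE)
  atom <- lines[3:(2 + n)]
  pos <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    ln <- atom[k]
    if (nchar(ln) < 44)
      stop(sprintf("%s: line %d: short atom record", path, k + 2),
           call. = FALSE)
    pos[k, ] <- as.numeric(c(substr(ln, 21, 28), substr(ln, 29, 36),
                             substr(ln, 37, 44)))
  }
  if (anyNA(pos))
    stop(sprintf("%s: non-numeric coordinate field", path), call. = FALSE)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]),
                                               "\\s+")[[1]]))
  if (length(boxv) < 3 || anyNA(boxv[1:3]))
    stop(sprintf("%s: missing or invalid box line", path), call. = FALSE)
  if (max(abs(boxv[1:3] - boxv[1])) > 1e-6)
    stop(sprintf("%s: only cubic boxes are supported", path), call. = FALSE)
  list(frame = bead_frame(pos, box = boxv[1]),
       atom_names = trimws(substr(atom, 11, 15)),
       res_names = trimws(substr(atom, 6, 10)))
}

#' Write a bead frame as a GRO coordinate file
#'
#' @param frame a [bead_frame].
#' @param path output path.
#' @param atom_names,res_names optional per-bead labels (default `CG`).
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, atom_names = NULL, res_names = NULL,
                      title = "gomech frame") {
  stopifnot(inherits(frame, "bead_frame"))
  n <- nrow(frame$positions)
  atom_names <- atom_names %||% rep("CG", n)
  res_names <- res_names %||% rep("CG", n)
  recs <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  seq_len(n) %% 100000L, res_names, atom_names,
                  seq_len(n) %% 100000L,
                  frame$positions[, 1], frame$positions[, 2],
                  frame$positions[, 3])
  writeLines(c(title, sprintf("%5d", n), recs,
               sprintf("%10.5f%10.5f%10.5f", frame$box, frame$box,
                       frame$box)),
             path)
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Plain XYZ blocks (count line, comment line, `name x y z` records).  The
#' comment line may carry `box=<nm>` and `time=<ns>`; otherwise `box` must
#' be given.
#'
#' @param path XYZ path.
#' @param box cubic box edge, nm (fallback if not in the comment lines).
#' @return list of [bead_frame]s.
#' @export
read_xyz <- function(path, box = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n))
      stop(sprintf("%s: line %d: expected an atom count", path, i),
           call. = FALSE)
    comment <- lines[i + 1L]
    get_tag <- function(tag) {
      m <- regmatches(comment,
                      regexec(paste0(tag, "=([0-9.eE+-]+)"), comment))[[1]]
      if (length(m) == 2) as.numeric(m[2]) else NULL
    }
    b <- get_tag("box") %||% box
    if (is.null(b))
      stop(sprintf("%s: no box on comment line %d and no 'box' argument",
                   path, i + 1L), call. = FALSE)
    rows <- lines[(i + 2L):(i + 1L + n)]
    m <- do.call(rbind, lapply(rows, function(ln) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      as.numeric(f[2:4])
    }))
    frames[[length(frames) + 1L]] <-
      bead_frame(m, box = b, time = get_tag("time") %||% (length(frames)))
    i <- i + 2L + n
  }
  frames
}

#' Write bead frames as a multi-frame XYZ trajectory
#'
#' @param frames a list of [bead_frame]s or a `cg_trajectory`.
#' @param path output path.
#' @param names per-bead element labels (default `CG`).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, names = NULL) {
  if (inherits(frames, "cg_trajectory")) frames <- frames$frames
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$positions)
    nm <- names %||% rep("CG", n)
    writeLines(c(sprintf("%d", n),
                 sprintf("box=%.10g time=%.10g", fr$box, fr$time),
                 sprintf("%-4s %.10g %.10g %.10g", nm,
                         fr$positions[, 1], fr$positions[, 2],
                         fr$positions[, 3])),
               con)
  }
  invisible(path)
}

#' Read a bead topology from CSV
#'
#' @param path CSV with header `bead_index,type,charge_e,group`.
#' @return a [topology].
#' @export
read_topology <- function(path) topology(utils::read.csv(path))

#' Write a bead topology to CSV
#' @param topo a [topology].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  utils::write.csv(as.data.frame(topo), path, row.names = FALSE)
  invisible(path)
}

#' Read a Lennard-Jones parameter table from CSV
#'
#' @param path CSV with header `type_a,type_b,sigma_nm,epsilon_kjmol`.
#' @return an [lj_table].
#' @export
read_lj_table <- function(path) lj_table(utils::read.csv(path))

#' Write the ground truth of a generated artifact as a JSON sidecar
#'
#' @param x an object produced by a `gen_*()` generator.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  gt <- ground_truth(x)
  if (is.null(gt)) stop("object carries no ground truth", call. = FALSE)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a q map (or any block grid) as CSV
#'
#' @param qmap a `q_map` or numeric matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_qmap_csv <- function(qmap, path) {
  m <- if (inherits(qmap, "q_map")) qmap$q else qmap
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

#' Write a q map as a PNG heat map
#'
#' @param qmap a `q_map`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_qmap_png <- function(qmap, path) {
  stopifnot(inherits(qmap, "q_map"))
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  m <- qmap$q
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  zlim = c(-1, 1), xlab = "block x", ylab = "block y",
                  main = "nematic order parameter q",
                  col = grDevices::hcl.colors(64, "viridis"))
  invisible(path)
}

#' Write a free-energy landscape as a CSV grid
#'
#' Long format: `x_center,y_center,F_kjmol,count` (empty bins omitted).
#'
#' @param landscape an `fe_landscape`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(landscape, path) {
  stopifnot(inherits(landscape, "fe_landscape"))
  occ <- which(!is.na(landscape$F), arr.ind = TRUE)
  df <- data.frame(x_center = landscape$x_centers[occ[, 1]],
                   y_center = landscape$y_centers[occ[, 2]],
                   F_kjmol = landscape$F[occ],
                   count = landscape$counts[occ])
  utils::write.csv(df[order(df$x_center, df$y_center), ], path,
                   row.names = FALSE)
  invisible(path)
}
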