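#' Read a molecular structure file
#'
#' Reads a single-frame structure in GRO (nm), PDB (Angstrom, converted to nm
#' on read) or XYZ (Angstrom) format into an [md_frame()]. Molecule indices
#' are inferred from residue numbering: a new (resid, resname) run starts a
#' new molecule. For XYZ files, which carry no residue metadata, each oxygen
#' starts a molecule and subsequent hydrogens attach to it.
#'
#' @param path file path.
#' @param format one of "gro", "pdb", "xyz"; inferred from the extension by
#'   default.
#' @param frame for multi-frame files, which frame to return (default first).
#' @return an `md_frame`.
#' @export
read_structure <- function(path, format = NULL, frame = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- .resolve_format(path, format)
  frames <- switch(format,
    gro = .read_gro(path),
    pdb = .read_pdb(path),
    xyz = .read_xyz(path)
  )
  if (!length(frames)) stop("empty trajectory: no frames in ", path)
  if (frame > length(frames)) stop("requested frame ", frame, " of ", length(frames))
  frames[[frame]]
}

#' Read a trajectory
#'
#' Accepts one multi-frame file (concatenated GRO/XYZ frames or PDB MODEL
#' blocks) or an ordered character vector of single-frame files. Frame times
#' are taken from the file where present (GRO `t=` in the title line);
#' missing times are filled from `dt`.
#'
#' @param paths one path or an ordered vector of paths.
#' @param format format string as in [read_structure()].
#' @param dt frame spacing in ns used to fill missing times.
#' @return an `md_trajectory`.
#' @export
read_trajectory <- function(paths, format = NULL, dt = NULL) {
  frames <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p)
    fmt <- .resolve_format(p, format)
    frames <- c(frames, switch(fmt,
      gro = .read_gro(p),
      pdb = .read_pdb(p),
      xyz = .read_xyz(p)
    ))
  }
  if (!length(frames)) stop("empty trajectory: no frames read")
  times <- vapply(frames, function(f) f$time, numeric(1))
  have_times <- length(frames) == 1L || all(diff(times) > 0)
  md_trajectory(frames, times = if (have_times) times else NULL, dt = dt)
}

#' Write a structure file
#'
#' Writes an [md_frame()] in GRO (nm, 3 decimals), PDB (Angstrom) or XYZ
#' (Angstrom) format. Atom and residue serials are written 1-based.
#'
#' @param frame an `md_frame`.
#' @param path output path.
#' @param format as in [read_structure()].
#' @param append append as an extra frame (multi-frame trajectories by
#'   concatenation).
#' @return `path`, invisibly.
#' @export
write_structure <- function(frame, path, format = NULL, append = FALSE) {
  format <- .resolve_format(path, format)
  switch(format,
    gro = .write_gro(frame, path, append),
    pdb = .write_pdb(frame, path, append),
    xyz = .write_xyz(frame, path, append)
  )
  invisible(path)
}

.resolve_format <- function(path, format) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  if (!format %in% c("gro", "pdb", "xyz")) {
    stop("unsupported format: '", format, "' (supported: gro, pdb, xyz)")
  }
  format
}

# ---- GRO ----

.read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    if (i + 1L > length(lines)) stop("GRO parse error at line ", i, ": truncated header")
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 0L) stop("GRO parse error at line ", i + 1L, ": bad atom count")
    if (i + 1L + nat + 1L > length(lines)) {
      stop("GRO parse error at line ", i + 1L, ": atom count exceeds file length")
    }
    body <- lines[(i + 2L):(i + 1L + nat)]
    resid <- suppressWarnings(as.integer(substr(body, 1, 5)))
    resname <- trimws(substr(body, 6, 10))
    name <- trimws(substr(body, 11, 15))
    xs <- suppressWarnings(as.numeric(substr(body, 21, 28)))
    ys <- suppressWarnings(as.numeric(substr(body, 29, 36)))
    zs <- suppressWarnings(as.numeric(substr(body, 37, 44)))
    bad <- which(is.na(resid) | is.na(xs) | is.na(ys) | is.na(zs))
    if (length(bad)) {
      stop("GRO parse error at line ", i + 1L + bad[1L], ": malformed atom record")
    }
    boxline <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]]))
    if (length(boxline) < 3L || any(is.na(boxline[1:3]))) {
      stop("GRO parse error at line ", i + 2L + nat, ": malformed box line")
    }
    tm <- 0
    m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(m)) tm <- as.numeric(sub("t=\\s*", "", m)) / 1000  # GRO t= is ps
    frames[[length(frames) + 1L]] <- md_frame(
      positions = cbind(xs, ys, zs),
      box = boxline[1:3],
      atoms = data.frame(name = name, resname = resname, resid = resid,
                         molid = .molid_from_residues(resid, resname)),
      time = tm
    )
    i <- i + nat + 3L
  }
  frames
}

.write_gro <- function(frame, path, append = FALSE) {
  at <- frame$atoms
  p <- frame$positions
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(sprintf("generated by afpice, t= %.3f", frame$time * 1000), con)
  writeLines(sprintf("%5d", nrow(p)), con)
  resid1 <- ((at$resid - 1L) %% 99999L) + 1L
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     resid1, substr(at$resname, 1, 5), substr(at$name, 1, 5),
                     ((seq_len(nrow(p)) - 1L) %% 99999L) + 1L,
                     p[, 1], p[, 2], p[, 3]), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3]), con)
}

# ---- PDB ----

.read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  box <- NULL
  cr <- which(rec == "CRYST1")
  if (length(cr)) {
    v <- suppressWarnings(as.numeric(c(substr(lines[cr[1]], 7, 15),
                                       substr(lines[cr[1]], 16, 24),
                                       substr(lines[cr[1]], 25, 33))))
    if (!any(is.na(v))) box <- v / 10
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_id <- cumsum(rec == "MODEL ")
  if (!any(is_atom)) stop("PDB parse error: no ATOM/HETATM records in ", path)
  groups <- split(which(is_atom), model_id[is_atom])
  lapply(groups, function(ii) {
    b <- lines[ii]
    name <- trimws(substr(b, 13, 16))
    alt <- substr(b, 17, 17)
    resname <- trimws(substr(b, 18, 20))
    resid <- suppressWarnings(as.integer(substr(b, 23, 26)))
    xs <- suppressWarnings(as.numeric(substr(b, 31, 38)))
    ys <- suppressWarnings(as.numeric(substr(b, 39, 46)))
    zs <- suppressWarnings(as.numeric(substr(b, 47, 54)))
    bad <- which(is.na(resid) | is.na(xs) | is.na(ys) | is.na(zs))
    if (length(bad)) stop("PDB parse error at line ", ii[bad[1L]], ": malformed ATOM record")
    keep <- alt %in% c(" ", "A")  # first altloc only
    pos <- cbind(xs, ys, zs)[keep, , drop = FALSE] / 10
    bx <- box
    if (is.null(bx)) {
      ext <- apply(pos, 2, function(v) diff(range(v)))
      bx <- pmax(ext + 1, 1)  # non-periodic fallback: pad by 1 nm
    }
    md_frame(
      positions = pos,
      box = bx,
      atoms = data.frame(name = name[keep], resname = resname[keep],
                         resid = resid[keep],
                         molid = .molid_from_residues(resid[keep], resname[keep])),
      time = 0
    )
  })
}

.write_pdb <- function(frame, path, append = FALSE) {
  at <- frame$atoms
  p <- frame$positions * 10  # nm -> Angstrom
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10), con)
  el <- substr(trimws(at$name), 1, 1)
  writeLines(sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     ((seq_len(nrow(p)) - 1L) %% 99999L) + 1L,
                     substr(at$name, 1, 4), substr(at$resname, 1, 3),
                     ((at$resid - 1L) %% 9999L) + 1L,
                     p[, 1], p[, 2], p[, 3], el), con)
  writeLines("END", con)
}

# ---- XYZ ----

.read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("XYZ parse error at line ", i, ": expected atom count")
    if (i + 1L + nat > length(lines)) stop("XYZ parse error at line ", i, ": truncated frame")
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad)) stop("XYZ parse error at line ", i + 1L + bad[1L], ": malformed record")
    el <- vapply(toks, `[[`, character(1), 1L)
    pos <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3))) / 10
    if (any(is.na(pos))) stop("XYZ parse error: non-numeric coordinate in frame at line ", i)
    m <- regmatches(comment, regexpr("box\\s*=\\s*[0-9.eE+ -]+", comment))
    if (length(m)) {
      bx <- as.numeric(strsplit(trimws(sub("box\\s*=\\s*", "", m)), "\\s+")[[1]])[1:3]
    } else {
      ext <- apply(pos, 2, function(v) diff(range(v)))
      bx <- pmax(ext + 1, 1)
    }
    # O starts a molecule; H attaches to the current one; other elements are
    # one molecule per atom.
    molid <- integer(nat); cur <- -1L
    for (k in seq_len(nat)) {
      if (toupper(el[k]) == "H" && cur >= 0L) molid[k] <- cur
      else { cur <- cur + 1L; molid[k] <- cur }
    }
    nm <- el
    nm[toupper(el) == "O"] <- "OW"
    hsel <- toupper(el) == "H"
    nm[hsel] <- paste0("HW", ave(seq_len(nat)[hsel], molid[hsel], FUN = seq_along))
    frames[[length(frames) + 1L]] <- md_frame(
      positions = pos, box = bx,
      atoms = data.frame(name = nm, resname = ifelse(toupper(el) %in% c("O", "H"), "SOL", el),
                         resid = molid + 1L, molid = molid),
      time = 0
    )
    i <- i + nat + 2L
  }
  frames
}

.write_xyz <- function(frame, path, append = FALSE) {
  p <- frame$positions * 10
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(sprintf("%d", nrow(p)), con)
  writeLines(sprintf("box = %.4f %.4f %.4f (A), t = %g ns",
                     frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10, frame$time), con)
  el <- substr(trimws(frame$atoms$name), 1, 1)
  writeLines(sprintf("%-2s %12.5f %12.5f %12.5f", el, p[, 1], p[, 2], p[, 3]), con)
}

# New molecule wherever the (resid, resname) pair changes between consecutive
# atoms; 0-based.
.molid_from_residues <- function(resid, resname) {
  if (!length(resid)) return(integer())
  key <- paste(resid, resname)
  cumsum(c(TRUE, key[-1] != key[-length(key)])) - 1L
}
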