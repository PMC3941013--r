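## Text formats: XVG-like whitespace-separated numeric traces with '#'
## comments and '@' metadata lines, multi-model PDB for hexamer
## trajectories (via bio3d), and JSON results.

parse_trace_lines <- function(lines, path) {
  is_hdr <- grepl("^\\s*[#@]", lines) | !nzchar(trimws(lines))
  meta <- list()
  for (ln in lines[grepl("^\\s*@", lines)]) {
    tok <- strsplit(trimws(sub("^\\s*@\\s*", "", ln)), "\\s+")[[1]]
    if (length(tok) >= 2) {
      val <- suppressWarnings(as.numeric(tok[2]))
      meta[[tok[1]]] <- if (is.na(val)) paste(tok[-1], collapse = " ") else val
    }
  }
  data_idx <- which(!is_hdr)
  if (length(data_idx) == 0)
    stop("no data rows in ", path)
  rows <- strsplit(trimws(lines[data_idx]), "\\s+")
  ncol <- length(rows[[1]])
  bad <- which(lengths(rows) != ncol)
  if (length(bad))
    stop("ragged row in ", path, " at line ", data_idx[bad[1]],
         ": expected ", ncol, " fields, found ", lengths(rows)[bad[1]])
  m <- suppressWarnings(
    matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE))
  if (anyNA(m)) {
    bad_row <- which(apply(is.na(m), 1, any))[1]
    stop("non-numeric field in ", path, " at line ", data_idx[bad_row])
  }
  list(data = m, meta = meta,
       header = lines[is_hdr & grepl("^\\s*#", lines)])
}

#' Read an XVG-like numeric trace file
#'
#' Lines starting with `#` are comments, lines starting with `@` are
#' `key value` metadata; the rest are whitespace-separated numeric
#' columns with a constant column count. Parse failures report the
#' offending line number.
#'
#' @param path file path.
#' @param columns character vector naming the column roles, e.g.
#'   `c("z", "W")` or `c("t", "z_trap", "z_ion", "F_spring")`.
#' @param as output type: `"table"` (plain data frame), `"pmf"`
#'   (a [pmf_profile()]; needs columns `z`, `W`), `"smd"` (an
#'   [smd_log()]; needs `t`, `z_trap`, `z_ion`, `F_spring` and metadata
#'   `k`, `v`), `"pull"` (a [pull_trace_set()]; needs `t` plus one column
#'   per trace and metadata `k`, `v`).
#' @return The typed object; `@` metadata is attached as attribute
#'   `meta`, `#` header lines as attribute `header`.
#' @export
read_trace <- function(path, columns = NULL,
                       as = c("table", "pmf", "smd", "pull")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path)
  pr <- parse_trace_lines(readLines(path), path)
  if (is.null(columns)) {
    columns <- if (!is.null(pr$meta$columns))
      strsplit(pr$meta$columns, ",")[[1]]
    else switch(as,
      pmf = c("z", "W"),
      smd = c("t", "z_trap", "z_ion", "F_spring"),
      pull = c("t", paste0("F", seq_len(ncol(pr$data) - 1))),
      paste0("V", seq_len(ncol(pr$data))))
  }
  if (length(columns) != ncol(pr$data))
    stop(path, ": ", ncol(pr$data), " columns but ", length(columns),
         " roles declared")
  df <- as.data.frame(pr$data)
  names(df) <- columns
  need_kv <- function() {
    if (is.null(pr$meta$k) || is.null(pr$meta$v))
      stop(path, ": '@ k <value>' and '@ v <value>' metadata required")
  }
  out <- switch(as,
    table = df,
    pmf = {
      stopifnot(all(c("z", "W") %in% columns))
      tag <- if (!is.null(pr$meta$tag)) pr$meta$tag else "hemichannel"
      pmf_profile(df$z, df$W, tag = tag)
    },
    smd = {
      stopifnot(all(c("t", "z_trap", "z_ion", "F_spring") %in% columns))
      need_kv()
      smd_log(df$t, df$z_trap, df$z_ion, df$F_spring,
              k = pr$meta$k, v = pr$meta$v)
    },
    pull = {
      stopifnot("t" %in% columns)
      need_kv()
      fc <- setdiff(columns, "t")
      pull_trace_set(lapply(fc, function(cn) data.frame(t = df$t, F = df[[cn]])),
                     k = pr$meta$k, v = pr$meta$v,
                     condition = pr$meta$condition)
    })
  attr(out, "meta") <- pr$meta
  attr(out, "header") <- pr$header
  out
}

#' Write a numeric object in the XVG-like trace dialect
#'
#' Writes `#` unit headers, `@` metadata and the data columns at full
#' double precision (`%.12g`), so `read_trace(write_trace(x))` round-trips
#' bit-comparably at the printed precision.
#'
#' @param x a [pmf_profile()], [smd_log()], [pull_trace_set()] or plain
#'   data frame.
#' @param path output file path.
#' @param meta extra named metadata written as `@` lines.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, meta = list()) {
  units_line <- "# units: nm, ns, kJ/mol, kJ mol-1 nm-1"
  if (inherits(x, "pmf_profile")) {
    df <- as.data.frame(x)
    meta <- c(list(tag = attr(x, "tag"), columns = "z,W"), meta)
  } else if (inherits(x, "smd_log")) {
    df <- as.data.frame(x)[, c("t", "z_trap", "z_ion", "F_spring")]
    meta <- c(list(k = attr(x, "k"), v = attr(x, "v"),
                   columns = "t,z_trap,z_ion,F_spring"), meta)
  } else if (inherits(x, "pull_trace_set")) {
    t0 <- x$traces[[1]]$t
    for (tr in x$traces)
      if (!isTRUE(all.equal(tr$t, t0)))
        stop("pull traces must share a common time base to be written ",
             "in one file; resample first")
    df <- data.frame(t = t0)
    for (i in seq_along(x$traces)) df[[paste0("F", i)]] <- x$traces[[i]]$F
    meta <- c(list(k = x$k, v = x$v,
                   columns = paste(names(df), collapse = ",")), meta)
    if (!is.null(x$condition)) meta$condition <- x$condition
  } else {
    df <- as.data.frame(x)
    meta <- c(list(columns = paste(names(df), collapse = ",")), meta)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(units_line, con)
  for (nm in names(meta))
    writeLines(paste("@", nm, format(meta[[nm]], digits = 15)), con)
  utils::write.table(format(df, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a multi-model PDB file as a hexamer trajectory
#'
#' Expects MODEL/ENDMDL frames with exactly 6 chains (protomers, cyclic
#' pore order = chain order) and an alpha carbon for every requested
#' residue in every chain. Coordinates are converted from Angstrom (PDB
#' convention) to nm at this boundary.
#'
#' @param path PDB file path.
#' @param residues residue numbers to extract.
#' @param chain_order optional explicit cyclic chain order; default is the
#'   order of first appearance.
#' @return A [hex_frame_series()].
#' @export
read_hex_pdb <- function(path, residues, chain_order = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  chains <- if (is.null(chain_order)) unique(atoms$chain) else chain_order
  if (length(chains) != 6)
    stop(path, ": expected 6 chains (protomers), found ", length(chains),
         " (", paste(chains, collapse = ", "), ")")
  nf <- nrow(pdb$xyz)
  coords <- array(NA_real_, dim = c(nf, 6, length(residues), 3))
  for (ci in seq_along(chains)) for (rj in seq_along(residues)) {
    sel <- which(atoms$chain == chains[ci] & atoms$resno == residues[rj] &
                   atoms$elety == "CA")
    if (length(sel) != 1)
      stop(path, ": chain ", chains[ci], " residue ", residues[rj],
           ": expected exactly one CA atom, found ", length(sel))
    cols <- (sel - 1) * 3 + 1:3
    coords[, ci, rj, ] <- pdb$xyz[, cols, drop = FALSE] / 10  # A -> nm
  }
  if (anyNA(coords)) {
    bad <- which(apply(is.na(coords), 1, any))
    stop(path, ": missing coordinates in model(s) ",
         paste(bad, collapse = ", "))
  }
  hex_frame_series(coords, residues = residues)
}

#' Write a hexamer trajectory as a multi-model PDB file
#'
#' One MODEL per frame, chains A-F (cyclic protomer order), one CA atom
#' per residue; coordinates converted from nm to Angstrom (3 decimals,
#' the PDB precision).
#'
#' @param traj a [hex_frame_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hex_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "hex_frame_series"))
  dims <- dim(traj$coords)
  chains <- LETTERS[1:6]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dims[1])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    for (ci in 1:6) for (rj in seq_len(dims[3])) {
      serial <- serial + 1L
      xyz <- traj$coords[f, ci, rj, ] * 10   # nm -> A
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, chains[ci], traj$residues[rj], xyz[1], xyz[2], xyz[3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write an analysis result as JSON
#'
#' @param x a list or result object (coerced with `unclass`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
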