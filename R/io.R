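#' Write configurations in extended-XYZ format
#'
#' One frame per block: particle count, a comment line carrying
#' `Lattice="..."`, `Properties=species:S:1:pos:R:3:charge:R:1` and
#' `Time=...`, then one line per particle. Positions are written with nine
#' decimals so a round-trip preserves them to well below 1e-6 nm.
#'
#' @param x a [particle_system()] or an `md_trajectory` (all frames).
#' @param path output file.
#' @param append append to an existing file.
#' @export
write_extxyz <- function(x, path, append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  emit <- function(pos, species, charge, box, time) {
    n <- nrow(pos)
    lat <- paste(sprintf("%.9g", c(box[1], 0, 0, 0, box[2], 0, 0, 0, box[3])),
                 collapse = " ")
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3:charge:R:1 Time=%.9g', lat,
      time), con)
    if (is.null(charge)) charge <- rep(0, n)
    writeLines(sprintf("%s %.9f %.9f %.9f %.9g", species,
                       pos[, 1], pos[, 2], pos[, 3], charge), con)
  }
  if (inherits(x, "particle_system")) {
    emit(x$positions, x$species, x$charges, x$box, x$time)
  } else if (inherits(x, "md_trajectory")) {
    for (i in seq_along(x$times))
      emit(x$positions[[i]], x$species, x$charges, x$boxes[i, ], x$times[i])
  } else stop("x must be a particle_system or md_trajectory")
  invisible(path)
}

#' Read extended-XYZ frames
#'
#' Parses every frame of an extended-XYZ file. The `Properties=` record in
#' the comment line is honoured, so foreign files with extra per-atom
#' columns are parsed and the extras preserved. A truncated final frame is
#' an error that names the last complete frame.
#'
#' @param path input file.
#' @return list of frames; each frame is a [particle_system()] (without
#'   topology) whose extra columns, if any, are stored in attribute
#'   `"extra"`.
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n))
      stop("malformed frame header at line ", i, ": ", lines[i])
    if (i + 1L + n > length(lines))
      stop("truncated file: frame ", length(frames) + 1,
           " incomplete; last complete frame is ", length(frames))
    comment <- lines[i + 1L]
    box <- parse_lattice(comment)
    prop <- parse_properties(comment)
    time <- parse_kv_num(comment, "Time", default = 0)
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    ncol_expect <- sum(prop$width)
    bad <- which(vapply(toks, length, 1L) < ncol_expect)
    if (length(bad))
      stop("malformed atom line ", i + 1L + bad[1], " (expected ",
           ncol_expect, " fields)")
    tab <- do.call(rbind, lapply(toks, function(t) t[seq_len(ncol_expect)]))
    col0 <- cumsum(c(0, prop$width))
    get_field <- function(name) {
      k <- which(prop$name == name)
      if (!length(k)) return(NULL)
      tab[, (col0[k] + 1):(col0[k] + prop$width[k]), drop = FALSE]
    }
    species <- as.vector(get_field("species"))
    pos <- apply(get_field("pos"), 2, as.numeric)
    if (is.null(species) || is.null(pos))
      stop("frame at line ", i, " lacks species/pos properties")
    chg <- get_field("charge")
    sys <- particle_system(matrix(pos, ncol = 3), species, box,
                           charges = if (!is.null(chg)) as.numeric(chg))
    sys$time <- time
    extras <- setdiff(prop$name, c("species", "pos", "charge"))
    if (length(extras)) {
      ex <- lapply(extras, get_field)
      names(ex) <- extras
      attr(sys, "extra") <- ex
    }
    frames[[length(frames) + 1L]] <- sys
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

parse_lattice <- function(comment) {
  m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (!length(m)) stop("comment line lacks a Lattice record")
  v <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", m), "[[:space:]]+")[[1]])
  if (length(v) != 9) stop("Lattice record must hold 9 numbers")
  c(v[1], v[5], v[9])
}

parse_properties <- function(comment) {
  m <- regmatches(comment, regexpr("Properties=[^ ]+", comment))
  if (!length(m)) # plain xyz default
    return(list(name = c("species", "pos"), width = c(1L, 3L)))
  p <- strsplit(sub("Properties=", "", m), ":")[[1]]
  if (length(p) %% 3 != 0) stop("malformed Properties record")
  idx <- seq(1, length(p), by = 3)
  list(name = p[idx], width = as.integer(p[idx + 2]))
}

parse_kv_num <- function(comment, key, default = NA_real_) {
  m <- regmatches(comment, regexpr(paste0(key, "=[^ ]+"), comment))
  if (!length(m)) return(default)
  as.numeric(sub(paste0(key, "="), "", m))
}

#' Write the topology sidecar
#'
#' Plain-text tabular sidecar with `[chains]`, `[bonds]`, `[angles]` and
#' `[sfcs]` sections (1-based particle indices), complementing the
#' extended-XYZ coordinate files.
#'
#' @param system a [particle_system()].
#' @param path output file.
#' @export
write_topology <- function(system, path) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- system$topology
  writeLines("# fibrilMD topology v1", con)
  writeLines("[chains]", con)
  writeLines(paste(seq_along(topo$chain),
                   ifelse(is.na(topo$chain), 0L, topo$chain)), con)
  writeLines("[bonds]", con)
  if (nrow(topo$bonds))
    writeLines(paste(topo$bonds$i, topo$bonds$j, topo$bonds$type), con)
  writeLines("[angles]", con)
  if (nrow(topo$angles))
    writeLines(paste(topo$angles$i, topo$angles$j, topo$angles$k,
                     topo$angles$type), con)
  writeLines("[sfcs]", con)
  if (nrow(topo$sfcs))
    writeLines(paste(topo$sfcs$chain, topo$sfcs$aa_i, topo$sfcs$aa_j,
                     topo$sfcs$first, topo$sfcs$last), con)
  invisible(path)
}

#' Read a topology sidecar
#'
#' @param path file written by [write_topology()].
#' @return a topology list (see [particle_system()]).
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  sec <- NULL
  chains <- list(); bonds <- list(); angles <- list(); sfcs <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "[")) { sec <- ln; next }
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (identical(sec, "[chains]")) chains[[length(chains) + 1]] <- f
    else if (identical(sec, "[bonds]")) bonds[[length(bonds) + 1]] <- f
    else if (identical(sec, "[angles]")) angles[[length(angles) + 1]] <- f
    else if (identical(sec, "[sfcs]")) sfcs[[length(sfcs) + 1]] <- f
    else stop("line outside a known section: ", ln)
  }
  ch <- if (length(chains)) {
    m <- do.call(rbind, chains)
    v <- as.integer(m[, 2]); v[v == 0L] <- NA_integer_
    v[order(as.integer(m[, 1]))]
  } else integer(0)
  bd <- if (length(bonds)) {
    m <- do.call(rbind, bonds)
    data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), type = m[, 3])
  } else data.frame(i = integer(), j = integer(), type = character())
  an <- if (length(angles)) {
    m <- do.call(rbind, angles)
    data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
               k = as.integer(m[, 3]), type = m[, 4])
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    type = character())
  sf <- if (length(sfcs)) {
    m <- do.call(rbind, sfcs)
    data.frame(chain = as.integer(m[, 1]), aa_i = as.integer(m[, 2]),
               aa_j = as.integer(m[, 3]), first = as.integer(m[, 4]),
               last = as.integer(m[, 5]))
  } else data.frame(chain = integer(), aa_i = integer(), aa_j = integer(),
                    first = integer(), last = integer())
  # AA bookkeeping is reconstructed from the SFC table
  aa_by_chain <- if (length(ch)) {
    ids <- sort(unique(ch[!is.na(ch)]))
    lapply(ids, function(cid)
      sort(unique(c(sf$aa_i[sf$chain == cid], sf$aa_j[sf$chain == cid]))))
  } else list()
  list(bonds = bd, angles = an, chain = ch, aa_by_chain = aa_by_chain,
       sfcs = sf)
}

#' Write an analysis table with a versioned header
#'
#' Tab-separated output with `#`-prefixed header lines recording the package
#' version and, when given, the configuration hash for exact re-runs.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param name table name recorded in the header.
#' @param config_hash optional configuration hash.
#' @export
write_analysis_table <- function(df, path, name = "table",
                                 config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fibrilMD %s %s",
                     as.character(utils::packageVersion("fibrilMD")), name),
             con)
  if (!is.null(config_hash)) writeLines(paste0("# config ", config_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an analysis table
#' @param path file written by [write_analysis_table()].
#' @export
read_analysis_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}
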