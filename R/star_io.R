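# Minimal RELION STAR reader/writer for particle metadata.
#
# Supports both the legacy single-block layout (data_ + loop_) and the
# RELION >= 3.1 layout with a data_optics block followed by data_particles.
# Only loop_ tables and simple key-value blocks are handled; values are kept
# as character strings so that pass-through columns survive a read/write
# round trip verbatim.

.default_column_map <- function() {
  list(id        = "rlnImageName",
       micrograph = "rlnMicrographName",
       rot       = "rlnAngleRot",
       tilt      = "rlnAngleTilt",
       psi       = "rlnAnglePsi",
       class     = c("rlnClassLabel", "rlnClassNumber"),
       optics_group = "rlnOpticsGroup",
       expansion = "rlnExpansionIndex")
}

# Parse a STAR file into a named list of blocks; each loop block becomes a
# character data.frame, each key-value block a named character vector.
parse_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  n <- length(lines)
  blocks <- list()
  i <- 1L
  skip_blank <- function(i) {
    while (i <= n && (lines[i] == "" || grepl("^#", lines[i]))) i <- i + 1L
    i
  }
  while (i <= n) {
    i <- skip_blank(i)
    if (i > n) break
    if (!grepl("^data_", lines[i]))
      stop(sprintf("malformed STAR file %s: expected data_ block at line %d",
                   path, i))
    name <- sub("^data_", "", lines[i])
    i <- skip_blank(i + 1L)
    if (i <= n && lines[i] == "loop_") {
      i <- skip_blank(i + 1L)
      cols <- character()
      while (i <= n && grepl("^_", lines[i])) {
        cols <- c(cols, sub("^_(\\S+).*$", "\\1", lines[i]))
        i <- i + 1L
      }
      rows <- list()
      while (i <= n && lines[i] != "" && !grepl("^data_", lines[i])) {
        if (!grepl("^#", lines[i])) {
          tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
          if (length(tok) != length(cols))
            stop(sprintf("STAR row with %d fields, expected %d (line %d of %s)",
                         length(tok), length(cols), i, path))
          rows[[length(rows) + 1L]] <- tok
        }
        i <- i + 1L
      }
      df <- if (length(rows)) {
        as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
      } else {
        as.data.frame(matrix(character(0), nrow = 0, ncol = length(cols)),
                      stringsAsFactors = FALSE)
      }
      names(df) <- cols
      blocks[[name]] <- df
    } else {
      kv <- character()
      while (i <= n && grepl("^_", lines[i])) {
        tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
        kv[sub("^_", "", tok[1])] <- paste(tok[-1], collapse = " ")
        i <- i + 1L
      }
      blocks[[name]] <- kv
    }
  }
  blocks
}

# Serialise blocks (as produced by parse_star) back to STAR text.
write_star_blocks <- function(blocks, path) {
  out <- c("# version 30001", "")
  for (name in names(blocks)) {
    b <- blocks[[name]]
    out <- c(out, paste0("data_", name), "")
    if (is.data.frame(b)) {
      out <- c(out, "loop_",
               sprintf("_%s #%d", names(b), seq_along(b)))
      if (nrow(b)) {
        mat <- as.matrix(b)
        out <- c(out, apply(mat, 1, paste, collapse = "\t"))
      }
    } else {
      out <- c(out, sprintf("_%s\t%s", names(b), unname(b)))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

.find_particles_block <- function(blocks, id_col) {
  if ("particles" %in% names(blocks) && is.data.frame(blocks[["particles"]]))
    return("particles")
  for (name in names(blocks)) {
    b <- blocks[[name]]
    if (is.data.frame(b) && id_col %in% names(b)) return(name)
  }
  for (name in names(blocks)) if (is.data.frame(blocks[[name]])) return(name)
  stop("no particles data block found")
}

#' Read one body's particle metadata from a STAR file
#'
#' Reads the particles block of a RELION STAR file (legacy single-block or
#' optics-group layout) into a half-table: one row per particle with the
#' Euler-angle triple of one focused refinement. All original columns are
#' retained for pass-through on write.
#'
#' @param path path to the STAR file.
#' @param column_map optional named list overriding the default RELION column
#'   names (`id`, `micrograph`, `rot`, `tilt`, `psi`, `class`,
#'   `optics_group`, `expansion`).
#' @return a data.frame of class `rotascape_half` with standardised columns
#'   `particle_id`, `micrograph`, `rot`, `tilt`, `psi`, `expansion_index`,
#'   `class`, `optics_group`; the raw STAR table and any optics block are
#'   kept in attributes `raw` and `optics`.
#' @details Duplicate identifiers (as produced by symmetry expansion) are
#'   disambiguated by `expansion_index` assigned in file order (first
#'   occurrence 0, second 1), unless the file carries an explicit expansion
#'   column.
#' @export
read_particle_star <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  cmap <- utils::modifyList(.default_column_map(), as.list(column_map %||% list()))
  blocks <- parse_star(path)
  pname <- .find_particles_block(blocks, cmap$id)
  raw <- blocks[[pname]]
  for (req in c("id", "rot", "tilt", "psi")) {
    col <- cmap[[req]][1]
    if (!col %in% names(raw))
      stop(sprintf("required column %s missing from %s", col, path))
  }
  if (nrow(raw) == 0) warning(sprintf("empty particles block in %s", path))
  pick <- function(key) {
    for (col in cmap[[key]]) if (col %in% names(raw)) return(raw[[col]])
    NULL
  }
  half <- data.frame(
    particle_id = raw[[cmap$id[1]]],
    micrograph = pick("micrograph") %||% rep(NA_character_, nrow(raw)),
    rot = as.numeric(raw[[cmap$rot[1]]]),
    tilt = as.numeric(raw[[cmap$tilt[1]]]),
    psi = as.numeric(raw[[cmap$psi[1]]]),
    stringsAsFactors = FALSE)
  exp_col <- pick("expansion")
  half$expansion_index <- if (!is.null(exp_col)) as.integer(exp_col) else
    stats::ave(seq_len(nrow(raw)), half$particle_id, FUN = seq_along) - 1L
  if (nrow(raw) == 0) half$expansion_index <- integer(0)
  cls <- pick("class")
  half$class <- if (!is.null(cls)) cls else rep(NA_character_, nrow(raw))
  og <- pick("optics_group")
  half$optics_group <- if (!is.null(og)) as.integer(og) else rep(NA_integer_, nrow(raw))
  if (!all(is.finite(half$rot)) && nrow(half) > 0 ||
      !all(is.finite(half$tilt)) && nrow(half) > 0 ||
      !all(is.finite(half$psi)) && nrow(half) > 0)
    stop(sprintf("non-numeric Euler angles in %s", path))
  attr(half, "raw") <- raw
  attr(half, "optics") <- if ("optics" %in% names(blocks)) blocks[["optics"]] else NULL
  attr(half, "source") <- path
  attr(half, "column_map") <- cmap
  class(half) <- c("rotascape_half", "data.frame")
  half
}

#' Pair the two focused refinements of one particle stack
#'
#' Inner join of the modifying-body and condensing-body half-tables on
#' `(particle_id, expansion_index)`. Because both refinements come from the
#' same stack, image names are expected to match exactly; counts of unmatched
#' entries on either side are reported as attributes and a message.
#'
#' @param table_mod half-table from the modifying-body refinement
#'   (the reference frame).
#' @param table_cond half-table from the condensing-body refinement.
#' @return a data.frame of class `particle_pairs` with both Euler triples per
#'   particle (`rot_mod`..`psi_mod`, `rot_cond`..`psi_cond`), class labels,
#'   and attributes `raw_mod`, `raw_cond`, `optics` for verbatim re-export.
#' @export
pair_refinements <- function(table_mod, table_cond) {
  if (nrow(table_mod) == 0 || nrow(table_cond) == 0)
    stop("cannot pair empty tables")
  for (tb in list(mod = table_mod, cond = table_cond)) {
    key <- paste(tb$particle_id, tb$expansion_index, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (particle_id, expansion_index) within one table; ",
           "set an expansion column or deduplicate first")
  }
  key_mod <- paste(table_mod$particle_id, table_mod$expansion_index, sep = "\r")
  key_cond <- paste(table_cond$particle_id, table_cond$expansion_index, sep = "\r")
  idx_cond <- match(key_mod, key_cond)
  sel_mod <- which(!is.na(idx_cond))
  if (length(sel_mod) == 0)
    stop("no shared identifiers between the two tables; ",
         "are these refinements of the same particle stack?")
  sel_cond <- idx_cond[sel_mod]
  n_un_mod <- nrow(table_mod) - length(sel_mod)
  n_un_cond <- nrow(table_cond) - length(sel_mod)
  if (n_un_mod + n_un_cond > 0)
    message(sprintf("pair_refinements: %d unmatched in modifying, %d in condensing",
                    n_un_mod, n_un_cond))
  paired <- data.frame(
    particle_id = table_mod$particle_id[sel_mod],
    expansion_index = table_mod$expansion_index[sel_mod],
    micrograph = table_mod$micrograph[sel_mod],
    rot_mod = table_mod$rot[sel_mod],
    tilt_mod = table_mod$tilt[sel_mod],
    psi_mod = table_mod$psi[sel_mod],
    rot_cond = table_cond$rot[sel_cond],
    tilt_cond = table_cond$tilt[sel_cond],
    psi_cond = table_cond$psi[sel_cond],
    class_mod = table_mod$class[sel_mod],
    class_cond = table_cond$class[sel_cond],
    optics_group = table_mod$optics_group[sel_mod],
    stringsAsFactors = FALSE)
  raw_mod <- attr(table_mod, "raw"); raw_cond <- attr(table_cond, "raw")
  attr(paired, "raw_mod") <- if (!is.null(raw_mod)) raw_mod[sel_mod, , drop = FALSE]
  attr(paired, "raw_cond") <- if (!is.null(raw_cond)) raw_cond[sel_cond, , drop = FALSE]
  attr(paired, "optics") <- attr(table_cond, "optics") %||% attr(table_mod, "optics")
  attr(paired, "unmatched") <- c(mod = n_un_mod, cond = n_un_cond)
  attr(paired, "provenance") <- c(mod = attr(table_mod, "source") %||% NA_character_,
                                  cond = attr(table_cond, "source") %||% NA_character_)
  class(paired) <- c("particle_pairs", "data.frame")
  paired
}

# Format angles the way RELION prints them.
.fmt_angle <- function(x) sprintf("%.6f", x)

# Build the raw particles data.frame for one body of a paired (or half)
# table, reusing pass-through columns when available.
.body_raw <- function(table, body) {
  if (inherits(table, "rotascape_half")) {
    raw <- attr(table, "raw")
    cmap <- attr(table, "column_map") %||% .default_column_map()
    ang <- cbind(table$rot, table$tilt, table$psi)
    cols <- c(cmap$rot[1], cmap$tilt[1], cmap$psi[1])
  } else {
    body <- match.arg(body, c("modifying", "condensing"))
    suf <- if (body == "modifying") "mod" else "cond"
    raw <- attr(table, paste0("raw_", suf))
    cmap <- .default_column_map()
    ang <- cbind(table[[paste0("rot_", suf)]],
                 table[[paste0("tilt_", suf)]],
                 table[[paste0("psi_", suf)]])
    cols <- c(cmap$rot[1], cmap$tilt[1], cmap$psi[1])
  }
  if (is.null(raw)) {
    raw <- data.frame(rlnImageName = table$particle_id,
                      stringsAsFactors = FALSE)
    if (!all(is.na(table$micrograph)))
      raw$rlnMicrographName <- table$micrograph
    raw$rlnAngleRot <- .fmt_angle(ang[, 1])
    raw$rlnAngleTilt <- .fmt_angle(ang[, 2])
    raw$rlnAnglePsi <- .fmt_angle(ang[, 3])
    raw$rlnExpansionIndex <- as.character(table$expansion_index)
    cls <- if (inherits(table, "rotascape_half")) table$class else
      table[[if (identical(body, "modifying")) "class_mod" else "class_cond"]]
    if (!all(is.na(cls))) raw$rlnClassLabel <- cls
    if (!all(is.na(table$optics_group)))
      raw$rlnOpticsGroup <- as.character(table$optics_group)
  } else {
    for (k in seq_along(cols)) {
      if (!cols[k] %in% names(raw))
        stop(sprintf("pass-through table lost angle column %s", cols[k]))
      raw[[cols[k]]] <- .fmt_angle(ang[, k])
    }
  }
  raw
}

#' Write particle metadata to a STAR file
#'
#' Writes a valid RELION particles STAR file whose Euler-angle columns are
#' the selected body's triples (formatted to six decimals); all other columns
#' of the source file, and any optics block, are passed through verbatim so
#' the output remains consumable by external reconstruction tools.
#'
#' @param table a half-table or paired `particle_pairs` table.
#' @param path output file path.
#' @param body which body's angles to write for a paired table:
#'   `"condensing"` (default; the reconstruction convention) or
#'   `"modifying"`. Ignored for half-tables.
#' @return `path`, invisibly.
#' @export
write_particle_star <- function(table, path, body = c("condensing", "modifying")) {
  body <- match.arg(body)
  if (nrow(table) == 0) stop("refusing to write an empty particle table")
  raw <- .body_raw(table, body)
  blocks <- list()
  optics <- attr(table, "optics")
  if (!is.null(optics)) blocks[["optics"]] <- optics
  blocks[["particles"]] <- raw
  write_star_blocks(blocks, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
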