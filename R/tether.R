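# Tether-reach analysis: can the carrier protein's phosphopantetheine arm,
# anchored on the static modifying wing, reach a catalytic site on the
# swivelling condensing wing at a given swivel angle alpha?
#
# The condensing body is rotated by alpha about the pivot axis (the
# landscape z axis) through the pivot point; the anchor stays fixed. A site
# is accessible when its anchor distance does not exceed the tether budget
# (default 80 A, the estimated maximum reach of the arm: linker stretch +
# ACP size + phosphopantetheine length).

#' Construct a tether model
#'
#' @param anchor numeric xyz (Angstrom) of the tether anchor on the static
#'   body (e.g. the CA of the residue where ACP is linked to KR).
#' @param sites named list of numeric xyz site coordinates on the rotating
#'   body (e.g. `KS` = the catalytic cysteine, `MAT` = the catalytic
#'   serine; same-side and opposite-side copies may both be given).
#' @param pivot_point numeric xyz the pivot axis passes through.
#' @param pivot_axis axis of the swivel rotation; normalised internally but
#'   must be non-degenerate and, if near-unit input is expected, within
#'   `1e-9` of unit length when `strict = TRUE`.
#' @param max_reach tether budget in Angstrom (default 80).
#' @param strict require `pivot_axis` to arrive unit-length.
#' @return an object of class `tether_model`.
#' @export
tether_model <- function(anchor, sites, pivot_point = c(0, 0, 0),
                         pivot_axis = c(0, 0, 1), max_reach = 80,
                         strict = TRUE) {
  nrm <- sqrt(sum(pivot_axis^2))
  if (nrm == 0) stop("pivot_axis must be non-zero")
  if (strict && abs(nrm - 1) >= 1e-9)
    stop("pivot_axis must be a unit vector")
  if (max_reach <= 0) stop("max_reach must be positive")
  if (is.null(names(sites)) || anyDuplicated(names(sites)) ||
      any(names(sites) == ""))
    stop("sites must carry unique names")
  model <- list(anchor = as.numeric(anchor),
                sites = lapply(sites, as.numeric),
                pivot_point = as.numeric(pivot_point),
                pivot_axis = pivot_axis / nrm,
                max_reach = max_reach)
  class(model) <- "tether_model"
  model
}

# Parse a "chain/resno/atom" selector.
.parse_selector <- function(sel) {
  parts <- strsplit(sel, "/", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop(sprintf("selector '%s' must be chain/resno/atom", sel))
  list(chain = parts[1], resno = as.integer(parts[2]), elety = parts[3])
}

.select_one_atom <- function(pdb, sel_string) {
  s <- .parse_selector(sel_string)
  sel <- bio3d::atom.select(pdb, chain = s$chain, resno = s$resno,
                            elety = s$elety, verbose = FALSE)
  n <- length(sel$atom)
  if (n != 1) {
    hits <- if (n == 0) "none" else
      paste(apply(pdb$atom[sel$atom, c("chain", "resno", "elety")], 1,
                  paste, collapse = "/"), collapse = ", ")
    stop(sprintf("selector '%s' matched %d atoms (%s); need exactly one",
                 sel_string, n, hits))
  }
  as.numeric(pdb$atom[sel$atom, c("x", "y", "z")])
}

#' Load a tether model from an atomic structure
#'
#' Extracts the anchor and catalytic-site coordinates from a PDB or mmCIF
#' file using `chain/resno/atom` selectors (e.g. `"A/2112/CA"` for the
#' anchor, `"A/161/SG"` for a catalytic cysteine).
#'
#' @param structure path to a `.pdb` or `.cif` file.
#' @param anchor selector string for the anchor atom.
#' @param sites named character vector of selector strings.
#' @param pivot_point,pivot_axis,max_reach,strict passed to
#'   [tether_model()].
#' @return a `tether_model`.
#' @export
load_sites <- function(structure, anchor, sites,
                       pivot_point = c(0, 0, 0), pivot_axis = c(0, 0, 1),
                       max_reach = 80, strict = TRUE) {
  if (!file.exists(structure)) stop(sprintf("no such file: %s", structure))
  pdb <- if (grepl("\\.cif$", structure, ignore.case = TRUE))
    bio3d::read.cif(structure, verbose = FALSE)
  else bio3d::read.pdb(structure, verbose = FALSE)
  site_xyz <- lapply(sites, .select_one_atom, pdb = pdb)
  names(site_xyz) <- names(sites)
  tether_model(anchor = .select_one_atom(pdb, anchor), sites = site_xyz,
               pivot_point = pivot_point, pivot_axis = pivot_axis,
               max_reach = max_reach, strict = strict)
}

# Rodrigues rotation of points about the model's pivot axis.
.rotate_about_pivot <- function(model, xyz, alpha_deg) {
  u <- model$pivot_axis
  v <- xyz - model$pivot_point
  t <- deg2rad(alpha_deg); c <- cos(t); s <- sin(t)
  ux <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  vv <- outer(c, v) + outer(s, ux) + outer((1 - c) * sum(u * v), u)
  sweep(vv, 2, model$pivot_point, "+")
}

#' Anchor-to-site distance as a function of the swivel angle
#'
#' Rotates the site by `alpha` about the pivot axis through the pivot point
#' (the condensing body swivels; the anchor sits on the static modifying
#' body) and returns the Euclidean anchor distance. Vectorised over
#' `alpha`; periodic with period 360.
#'
#' @param model a `tether_model`.
#' @param site site name.
#' @param alpha swivel angle(s) in degrees.
#' @return numeric vector of distances in Angstrom.
#' @export
distance_at_alpha <- function(model, site, alpha) {
  if (!site %in% names(model$sites))
    stop(sprintf("unknown site '%s'; available: %s", site,
                 paste(names(model$sites), collapse = ", ")))
  p <- .rotate_about_pivot(model, model$sites[[site]], alpha)
  sqrt(rowSums(sweep(p, 2, model$anchor)^2))
}

# Contiguous TRUE runs over a circular sample of alpha values; returns a
# data.frame(start, end) in degrees (start > end marks a wrap across 180).
.circular_intervals <- function(alphas, flag) {
  n <- length(flag)
  if (!any(flag)) return(data.frame(start = numeric(0), end = numeric(0)))
  if (all(flag)) return(data.frame(start = -180, end = 180))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- data.frame(start = alphas[starts[r$values]], end = alphas[ends[r$values]])
  if (flag[1] && flag[n]) {          # merge the run that crosses +/-180
    iv$start[1] <- iv$start[nrow(iv)]
    iv <- iv[-nrow(iv), , drop = FALSE]
  }
  rownames(iv) <- NULL
  iv
}

#' Scan site accessibility over the swivel angle
#'
#' Samples anchor-to-site distances over a full turn of alpha, flags each
#' site accessible where the distance is within the tether budget, and
#' reports, per site, the maximal contiguous accessible alpha intervals as
#' well as their intersection over all sites (the range in which the arm
#' can engage every site).
#'
#' @param model a `tether_model`.
#' @param step alpha sampling step in degrees (default 1).
#' @param max_reach tether budget; defaults to the model's.
#' @return list with `scan` (data.frame: `alpha`, `dist_<site>`,
#'   `accessible_<site>` columns), `intervals` (named list of per-site
#'   interval data.frames), and `all_sites` (intersection intervals).
#' @export
reach_scan <- function(model, step = 1, max_reach = model$max_reach) {
  if (step <= 0) stop("step must be positive")
  alphas <- seq(-180 + step, 180, by = step)
  scan <- data.frame(alpha = alphas)
  flags <- list()
  for (s in names(model$sites)) {
    d <- distance_at_alpha(model, s, alphas)
    scan[[paste0("dist_", s)]] <- d
    flags[[s]] <- d <= max_reach
    scan[[paste0("accessible_", s)]] <- flags[[s]]
  }
  intervals <- lapply(flags, function(f) .circular_intervals(alphas, f))
  all_flag <- Reduce(`&`, flags)
  list(scan = scan, intervals = intervals,
       all_sites = .circular_intervals(alphas, all_flag))
}
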