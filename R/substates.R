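# Recombination of symmetry-expanded per-monomer class labels into dimeric
# substates.
#
# Focused classification of each symmetry-expanded monomer assigns one
# condensing-wing label (five functional groups) and one modifying-wing
# label (psi-domains resolved or not) per asymmetric unit. Converting the
# expanded copies back to intact dimers gives unordered pairs of condensing
# labels (15 for five groups) crossed with sided psi-domain combinations
# (4), i.e. 60 dimeric substates.

#' Default condensing-wing monomer groups
#' @return character vector of the five functional ACP-engagement groups.
#' @export
condensing_groups <- function() {
  c("ACP-KS", "ACP-MAT", "ACP-in-transition", "no-ACP", "dynamic-MAT")
}

#' Modifying-wing monomer states
#' @return character vector of the two psi-domain states.
#' @export
modifying_states <- function() c("psi-resolved", "psi-unresolved")

#' Enumerate unordered condensing-wing label pairs
#'
#' All unordered pairs with repetition of `k` monomer groups:
#' `k * (k + 1) / 2` combinations (15 for the five functional groups).
#'
#' @param k number of monomer groups (generic `group-01`.. labels are
#'   generated), or a character vector of labels (default: the five
#'   functional ACP-engagement groups).
#' @return data.frame with columns `label_a`, `label_b` (canonical
#'   lexicographic order, `label_a <= label_b`) and `id`.
#' @export
enumerate_condensing_combos <- function(k = condensing_groups()) {
  labels <- if (is.character(k)) k else {
    if (!is.numeric(k) || k < 1) stop("k must be >= 1")
    sprintf("group-%02d", seq_len(k))
  }
  labels <- sort(unique(labels))
  n <- length(labels)
  if (n < 1) stop("need at least one monomer group")
  pairs <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, seq(i, n))))
  data.frame(label_a = labels[pairs[, 1]],
             label_b = labels[pairs[, 2]],
             id = paste(labels[pairs[, 1]], labels[pairs[, 2]], sep = "/"),
             stringsAsFactors = FALSE)
}

#' Enumerate sided modifying-wing combinations
#'
#' The dimeric modifying wing can have the psi-domains resolved on both
#' sides, on either single side, or on neither: four sided combinations.
#' With `collapse_sides = TRUE` the two single-side cases merge (unordered
#' reading), giving three.
#'
#' @param collapse_sides treat the two single-side combinations as one.
#' @return data.frame with columns `id` and `description`.
#' @export
enumerate_modifying_combos <- function(collapse_sides = FALSE) {
  combos <- data.frame(
    id = c("both", "side-A-only", "side-B-only", "neither"),
    description = c("psi-domains resolved on both sides",
                    "psi-domains resolved on side A only",
                    "psi-domains resolved on side B only",
                    "psi-domains resolved on neither side"),
    stringsAsFactors = FALSE)
  if (collapse_sides) {
    combos <- combos[combos$id != "side-B-only", , drop = FALSE]
    combos$id[combos$id == "side-A-only"] <- "one-side"
    combos$description[combos$id == "one-side"] <-
      "psi-domains resolved on exactly one side"
    rownames(combos) <- NULL
  }
  combos
}

#' Enumerate the full dimeric substate inventory
#'
#' Cartesian product of the unordered condensing pairs and the sided
#' modifying combinations: `k * (k + 1) / 2 * 4` substates (60 for five
#' condensing groups).
#'
#' @inheritParams enumerate_condensing_combos
#' @param collapse_sides passed to [enumerate_modifying_combos()].
#' @return data.frame with columns `label_a`, `label_b`, `modifying`, `id`.
#' @export
enumerate_full_substates <- function(k = condensing_groups(),
                                     collapse_sides = FALSE) {
  cc <- enumerate_condensing_combos(k)
  mc <- enumerate_modifying_combos(collapse_sides)
  out <- merge(cc, data.frame(modifying = mc$id), by = NULL)
  out$id <- paste(out$label_a, out$label_b, out$modifying, sep = "|")
  out <- out[order(out$label_a, out$label_b, out$modifying), ]
  rownames(out) <- NULL
  out[, c("label_a", "label_b", "modifying", "id")]
}

#' Assign the dimeric substate of one particle from its two expanded copies
#'
#' The two condensing labels are sorted into canonical (lexicographic)
#' order; side A is the copy whose condensing label sorts first, and the
#' modifying combination is keyed to that side assignment, so swapping the
#' two copies in the input yields the identical substate. When the two
#' condensing labels tie, the copy with resolved psi-domains is taken as
#' side A (making the id deterministic).
#'
#' @param cond_labels character(2): condensing labels of copies 1 and 2.
#' @param mod_labels character(2): modifying labels of copies 1 and 2
#'   (values of [modifying_states()]).
#' @param condensing_set valid condensing labels.
#' @return list with `label_a`, `label_b`, `modifying`, `id`.
#' @export
assign_substate <- function(cond_labels, mod_labels,
                            condensing_set = condensing_groups()) {
  if (length(cond_labels) != 2 || length(mod_labels) != 2)
    stop("need exactly the two expanded copies of one dimer")
  if (any(is.na(cond_labels)) || any(is.na(mod_labels)))
    stop("missing class label on one expanded copy")
  if (!all(cond_labels %in% condensing_set))
    stop(sprintf("unknown condensing label(s): %s",
                 paste(setdiff(cond_labels, condensing_set), collapse = ", ")))
  if (!all(mod_labels %in% modifying_states()))
    stop(sprintf("unknown modifying label(s): %s",
                 paste(setdiff(mod_labels, modifying_states()), collapse = ", ")))
  ord <- order(cond_labels, match(mod_labels, modifying_states()))
  ca <- cond_labels[ord[1]]; cb <- cond_labels[ord[2]]
  res <- mod_labels[ord] == "psi-resolved"
  modifying <- if (res[1] && res[2]) "both"
    else if (res[1]) "side-A-only"
    else if (res[2]) "side-B-only"
    else "neither"
  list(label_a = ca, label_b = cb, modifying = modifying,
       id = paste(ca, cb, modifying, sep = "|"))
}

#' Assign substates for a whole paired table
#'
#' Groups rows of a symmetry-expanded `particle_pairs` table by
#' `particle_id` (expecting the two expansion copies per dimer) and applies
#' [assign_substate()] to each dimer's condensing/modifying labels.
#'
#' @param pairs labelled `particle_pairs` table with both expansion copies.
#' @param condensing_set valid condensing labels.
#' @return data.frame with one row per dimer: `particle_id`, `label_a`,
#'   `label_b`, `modifying`, `substate_id`.
#' @export
assign_substates <- function(pairs, condensing_set = condensing_groups()) {
  sp <- split(seq_len(nrow(pairs)), pairs$particle_id)
  bad <- names(sp)[vapply(sp, length, integer(1)) != 2]
  if (length(bad))
    stop(sprintf("%d particle(s) lack exactly two expansion copies (e.g. %s)",
                 length(bad), bad[1]))
  rows <- lapply(sp, function(ix) {
    ix <- ix[order(pairs$expansion_index[ix])]
    s <- assign_substate(pairs$class_cond[ix], pairs$class_mod[ix],
                         condensing_set)
    data.frame(particle_id = pairs$particle_id[ix[1]],
               label_a = s$label_a, label_b = s$label_b,
               modifying = s$modifying, substate_id = s$id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Landscape of one dimeric substate
#'
#' Filters a labelled, symmetry-expanded paired table to the dimers assigned
#' to the given substate and builds their conformational landscape from the
#' expansion-index-0 copies (one point per dimer).
#'
#' @param pairs labelled `particle_pairs` table with both expansion copies.
#' @param substate_id canonical substate id (as in
#'   [enumerate_full_substates()]`$id` or [assign_substate()]`$id`).
#' @param bin_width,smooth_sigma passed to [build_landscape()].
#' @param canonicalize passed to [compute_orientations()].
#' @param condensing_set valid condensing labels.
#' @return a `landscape_grid` whose `n_particles` equals the number of
#'   dimers in the substate.
#' @export
substate_landscape <- function(pairs, substate_id, bin_width = 2,
                               smooth_sigma = 1, canonicalize = FALSE,
                               condensing_set = condensing_groups()) {
  assign <- assign_substates(pairs, condensing_set)
  ids <- assign$particle_id[assign$substate_id == substate_id]
  if (length(ids) == 0)
    stop(sprintf("no particles in substate %s", substate_id))
  sel <- pairs$particle_id %in% ids & pairs$expansion_index == 0L
  orients <- compute_orientations(pairs[sel, , drop = FALSE],
                                  canonicalize = canonicalize)
  build_landscape(orients, bin_width = bin_width, smooth_sigma = smooth_sigma)
}
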