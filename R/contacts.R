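#' Contact analysis parameters
#'
#' Defaults encode the persistent-contact definition used throughout:
#' heavy-atom distance not exceeding 3 Angstrom, with a contact called
#' persistent when present in at least 80% of the analysis-window frames
#' and very persistent at 90%. All thresholds are inclusive.
#'
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @param persistent Persistence fraction for the "persistent" class.
#' @param very_persistent Fraction for the "very_persistent" class.
#' @return A `contact_params` list.
#' @export
contact_params <- function(cutoff = 3.0, persistent = 0.80,
                           very_persistent = 0.90) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!(persistent > 0 && persistent <= very_persistent &&
        very_persistent <= 1))
    stop("need 0 < persistent <= very_persistent <= 1")
  structure(list(cutoff = cutoff, persistent = persistent,
                 very_persistent = very_persistent),
            class = "contact_params")
}

.classify_fraction <- function(fraction, params) {
  ifelse(fraction >= params$very_persistent, "very_persistent",
         ifelse(fraction >= params$persistent, "persistent", "poor"))
}

# All (i in a, j in b) atom index pairs closer than cutoff, brute force.
.close_pairs_brute <- function(xyz, ia, ib, cutoff) {
  A <- xyz[ia, , drop = FALSE]; B <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  hit <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
  cbind(ia[hit[, 1]], ib[hit[, 2]])
}

# Same contract via spatial binning: atoms are hashed into cubic cells of
# edge = cutoff and only the 27 neighbouring cells are scanned.
.close_pairs_cell <- function(xyz, ia, ib, cutoff) {
  all_idx <- c(ia, ib)
  P <- xyz[all_idx, , drop = FALSE]
  lo <- apply(P, 2, min)
  cell <- floor(sweep(P, 2, lo) / cutoff)
  key <- cell[, 1] + 4096 * (cell[, 2] + 4096 * cell[, 3])
  binB <- split(seq_along(ib) + length(ia), key[seq_along(ib) + length(ia)])
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", length(ia))
  for (k in seq_along(ia)) {
    ck <- cell[k, ]
    nb_keys <- (ck[1] + offsets[, 1]) +
      4096 * ((ck[2] + offsets[, 2]) + 4096 * (ck[3] + offsets[, 3]))
    cand <- unlist(binB[as.character(nb_keys)], use.names = FALSE)
    if (!length(cand)) next
    d2 <- rowSums(sweep(P[cand, , drop = FALSE], 2, P[k, ])^2)
    hit <- cand[d2 <= cutoff^2 + 1e-9]
    if (length(hit))
      out[[k]] <- cbind(ia[k], all_idx[hit])
  }
  do.call(rbind, c(out, list(matrix(integer(), 0, 2))))
}

#' Residue pairs in contact within one frame
#'
#' A residue pair is in contact when the minimum heavy-atom distance
#' between the two residues does not exceed the cutoff (inclusive).
#'
#' @param structure A [structure3d] (one trajectory frame).
#' @param selA,selB Disjoint selection strings (heavy atoms are taken
#'   from each).
#' @param cutoff Distance cutoff in Angstrom.
#' @param method "cell" (spatial binning) or "brute" (all pairs); both
#'   return identical sets.
#' @return data.frame with residue keys `key_a`, `key_b`
#'   ("chain:resid:resname") and the minimum distance `min_dist`.
#' @export
frame_contacts <- function(structure, selA, selB, cutoff = 3.0,
                           method = c("cell", "brute")) {
  method <- match.arg(method)
  atoms <- structure$atoms
  ia <- .heavy_only(structure, selA)
  ib <- .heavy_only(structure, selB)
  if (length(intersect(ia, ib)))
    stop("selection error: selections must be disjoint")
  pr <- if (method == "brute")
    .close_pairs_brute(structure$xyz, ia, ib, cutoff)
  else .close_pairs_cell(structure$xyz, ia, ib, cutoff)
  if (!nrow(pr))
    return(data.frame(key_a = character(), key_b = character(),
                      min_dist = numeric()))
  d <- sqrt(rowSums((structure$xyz[pr[, 1], , drop = FALSE] -
                     structure$xyz[pr[, 2], , drop = FALSE])^2))
  ka <- .residue_keys(atoms, pr[, 1]); kb <- .residue_keys(atoms, pr[, 2])
  agg <- tapply(d, paste(ka, kb, sep = "|"), min)
  keys <- strsplit(names(agg), "|", fixed = TRUE)
  data.frame(key_a = vapply(keys, `[`, "", 1),
             key_b = vapply(keys, `[`, "", 2),
             min_dist = as.numeric(agg), row.names = NULL)
}

.heavy_only <- function(structure, sel) {
  idx <- if (is.character(sel)) select_atoms(structure, sel) else sel
  if (!length(idx)) stop("selection error: empty selection")
  idx[!(structure$atoms$element[idx] %in% c("H", "D"))]
}

#' Contact persistence over an analysis window
#'
#' For every residue pair ever in contact within the window, the fraction
#' of window frames in which it is in contact, classified as
#' very_persistent (fraction >= 0.90), persistent (>= 0.80) or poor.
#' The denominator is the number of frames in the window.
#'
#' @param traj A [trajectory].
#' @param selA,selB Disjoint selections on the topology.
#' @param params A [contact_params].
#' @param window Integer vector of frame indices (default: all frames).
#' @param method Contact search method, see [frame_contacts()].
#' @return A `contact_table` data.frame: key_a, key_b, n_contact_frames,
#'   n_window_frames, fraction, class; attribute `window` records the
#'   frame range.
#' @export
contact_persistence <- function(traj, selA, selB, params = contact_params(),
                                window = NULL, method = "cell") {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(window)) window <- seq_along(traj$frames)
  if (!length(window)) stop("window error: empty analysis window")
  if (any(window < 1 | window > length(traj$frames)))
    stop("window error: frame indices outside the trajectory")
  ia <- .heavy_only(traj$topology, selA)
  ib <- .heavy_only(traj$topology, selB)
  counts <- new.env(parent = emptyenv())
  for (f in window) {
    fr <- structure3d(traj$topology$atoms, traj$frames[[f]])
    ct <- frame_contacts(fr, ia, ib, cutoff = params$cutoff, method = method)
    if (nrow(ct)) {
      k <- paste(ct$key_a, ct$key_b, sep = "|")
      for (kk in k)
        assign(kk, (if (exists(kk, counts)) get(kk, counts) else 0L) + 1L,
               counts)
    }
  }
  keys <- ls(counts)
  n <- vapply(keys, get, 0L, envir = counts)
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    key_a = vapply(parts, `[`, "", 1),
    key_b = vapply(parts, `[`, "", 2),
    n_contact_frames = as.integer(n),
    n_window_frames = length(window),
    fraction = as.numeric(n) / length(window),
    row.names = NULL)
  out$class <- .classify_fraction(out$fraction, params)
  out <- out[order(-out$fraction, out$key_a, out$key_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- range(window)
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Per-residue hotspot profile (histogram of contact percentages)
#'
#' Collapses a contact table to one record per residue of the first group
#' (optionally per partner chain): the residue's maximum persistence
#' fraction and its class. This is the per-residue hotspot histogram with
#' the usual colour key (green >= 90%, yellow 80-90%, red < 80%).
#'
#' @param table A `contact_table` from [contact_persistence()].
#' @param by_partner_chain Split records by the partner residue's chain?
#' @param params A [contact_params] (for the class thresholds).
#' @return data.frame: chain, resid, resname, partner_chain, max_fraction,
#'   class, colour.
#' @export
residue_profile <- function(table, by_partner_chain = TRUE,
                            params = contact_params()) {
  if (!nrow(table)) stop("empty contact table")
  pa <- do.call(rbind, strsplit(table$key_a, ":", fixed = TRUE))
  pchain <- vapply(strsplit(table$key_b, ":", fixed = TRUE), `[`, "", 1)
  grp <- if (by_partner_chain) paste(table$key_a, pchain) else table$key_a
  best <- tapply(seq_len(nrow(table)), grp,
                 function(ii) ii[which.max(table$fraction[ii])])
  ii <- as.integer(best)
  out <- data.frame(
    chain = pa[ii, 1], resid = as.integer(pa[ii, 2]), resname = pa[ii, 3],
    partner_chain = if (by_partner_chain) pchain[ii] else NA_character_,
    max_fraction = table$fraction[ii], row.names = NULL)
  out$class <- .classify_fraction(out$max_fraction, params)
  out$colour <- c(very_persistent = "green", persistent = "yellow",
                  poor = "red")[out$class]
  out[order(out$chain, out$resid, out$partner_chain), , drop = FALSE]
}

#' Water-mediated contact persistence
#'
#' A residue pair is bridged in a frame when at least one water oxygen lies
#' within `bridge_cutoff` of a heavy atom of both residues. Persistence is
#' aggregated exactly as in [contact_persistence()].
#'
#' @inheritParams contact_persistence
#' @param water_sel Selection for the bridging waters (oxygens are used).
#' @param bridge_cutoff Water-to-residue heavy-atom cutoff in Angstrom.
#' @return A `contact_table` (empty when no waters are selected).
#' @export
water_bridges <- function(traj, selA, selB, water_sel = "water",
                          bridge_cutoff = 3.5, params = contact_params(),
                          window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(window)) window <- seq_along(traj$frames)
  topo <- traj$topology
  iw <- select_atoms(topo, water_sel)
  iw <- iw[topo$atoms$element[iw] == "O"]
  empty <- data.frame(key_a = character(), key_b = character(),
                      n_contact_frames = integer(),
                      n_window_frames = integer(), fraction = numeric(),
                      class = character())
  class(empty) <- c("contact_table", "data.frame")
  if (!length(iw)) return(empty)
  ia <- .heavy_only(topo, selA); ib <- .heavy_only(topo, selB)
  ka <- .residue_keys(topo$atoms, ia); kb <- .residue_keys(topo$atoms, ib)
  counts <- list()
  for (f in window) {
    xyz <- traj$frames[[f]]
    pa <- .close_pairs_brute(xyz, iw, ia, bridge_cutoff)
    pb <- .close_pairs_brute(xyz, iw, ib, bridge_cutoff)
    if (!nrow(pa) || !nrow(pb)) next
    ra <- split(.residue_keys(topo$atoms, pa[, 2]), pa[, 1])
    rb <- split(.residue_keys(topo$atoms, pb[, 2]), pb[, 1])
    shared <- intersect(names(ra), names(rb))
    if (!length(shared)) next
    prs <- unique(do.call(rbind, lapply(shared, function(w)
      expand.grid(a = unique(ra[[w]]), b = unique(rb[[w]]),
                  stringsAsFactors = FALSE))))
    kk <- unique(paste(prs$a, prs$b, sep = "|"))
    for (k in kk) counts[[k]] <- (counts[[k]] %||% 0L) + 1L
  }
  if (!length(counts)) return(empty)
  parts <- strsplit(names(counts), "|", fixed = TRUE)
  out <- data.frame(
    key_a = vapply(parts, `[`, "", 1),
    key_b = vapply(parts, `[`, "", 2),
    n_contact_frames = as.integer(unlist(counts)),
    n_window_frames = length(window), row.names = NULL)
  out$fraction <- out$n_contact_frames / out$n_window_frames
  out$class <- .classify_fraction(out$fraction, params)
  out <- out[order(-out$fraction, out$key_a), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a contact table as TSV
#'
#' One row per residue pair with the residue key fields expanded:
#' chainA, residA, resnameA, chainB, residB, resnameB, n_contact_frames,
#' n_window_frames, fraction, class.
#'
#' @param table A `contact_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contact_table <- function(table, path) {
  a <- do.call(rbind, strsplit(as.character(table$key_a), ":", fixed = TRUE))
  b <- do.call(rbind, strsplit(as.character(table$key_b), ":", fixed = TRUE))
  if (is.null(a)) a <- matrix(character(), 0, 3)
  if (is.null(b)) b <- matrix(character(), 0, 3)
  out <- data.frame(chainA = a[, 1], residA = a[, 2], resnameA = a[, 3],
                    chainB = b[, 1], residB = b[, 2], resnameB = b[, 3],
                    n_contact_frames = table$n_contact_frames,
                    n_window_frames = table$n_window_frames,
                    fraction = table$fraction, class = table$class)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
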