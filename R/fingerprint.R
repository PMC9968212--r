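#' The eight protein-ligand interaction classes
#'
#' Fixed slot order (part of the fingerprint format contract):
#' hydrophobic contact, aromatic face-to-face, aromatic edge-to-face,
#' hydrogen bond with the protein as donor, hydrogen bond with the protein
#' as acceptor, salt bridge with the protein positively charged, salt
#' bridge with the protein negatively charged, and ionic bond with a
#' protein-bound metal ion.
#'
#' @return character vector of length 8.
#' @export
interaction_classes <- function() {
  c("hydrophobic", "aromatic_face_to_face", "aromatic_edge_to_face",
    "hbond_protein_donor", "hbond_protein_acceptor",
    "saltbridge_protein_positive", "saltbridge_protein_negative",
    "metal_ionic")
}

#' Geometric thresholds for interaction detection
#'
#' Defaults are conventional interaction-fingerprint cutoffs (ODDT-
#' compatible) and are frozen here for reproducibility; all are
#' configurable. Distances are heavy-atom distances in Angstrom, angles
#' in degrees.
#'
#' @param hydrophobic_dmax max distance between hydrophobic heavy atoms.
#' @param hbond_dmax max donor-acceptor heavy-atom distance.
#' @param hbond_angle_min min donor-H...acceptor angle (at the hydrogen);
#'   applied only when the donor has a recorded hydrogen.
#' @param saltbridge_dmax max cation-anion heavy-atom distance.
#' @param ring_centroid_dmax max aromatic ring centroid-centroid distance.
#' @param face_angle_max max inter-normal angle for face-to-face stacking.
#' @param edge_angle_range inter-normal angle window for edge-to-face.
#' @param metal_dmax max metal to ligand anion/acceptor distance.
#' @param warn_missing_h warn when a hydrogen bond falls back to the
#'   distance-only criterion because the donor has no recorded hydrogen.
#' @return object of class `ttmd_geometry_config`.
#' @export
geometry_config <- function(hydrophobic_dmax = 4.0, hbond_dmax = 3.5,
                            hbond_angle_min = 130, saltbridge_dmax = 4.0,
                            ring_centroid_dmax = 5.0, face_angle_max = 30,
                            edge_angle_range = c(60, 90), metal_dmax = 3.0,
                            warn_missing_h = TRUE) {
  cfg <- list(hydrophobic_dmax = hydrophobic_dmax, hbond_dmax = hbond_dmax,
              hbond_angle_min = hbond_angle_min, saltbridge_dmax = saltbridge_dmax,
              ring_centroid_dmax = ring_centroid_dmax, face_angle_max = face_angle_max,
              edge_angle_range = edge_angle_range, metal_dmax = metal_dmax,
              warn_missing_h = warn_missing_h)
  dists <- unlist(cfg[c("hydrophobic_dmax", "hbond_dmax", "saltbridge_dmax",
                        "ring_centroid_dmax", "metal_dmax")])
  if (any(dists <= 0)) stop("all distance thresholds must be > 0")
  angs <- c(hbond_angle_min, face_angle_max, edge_angle_range)
  if (any(angs < 0 | angs > 180)) stop("angles must lie in [0, 180]")
  structure(cfg, class = "ttmd_geometry_config")
}

#' Detect protein-ligand interactions in one frame
#'
#' Applies the geometric rules of the eight interaction classes to the
#' coordinates of `frame` (or the model's own coordinates when `frame` is
#' `NULL`). One row is emitted per interaction instance (per qualifying
#' atom pair or ring pair). When a donor has no recorded hydrogen the
#' hydrogen-bond test degrades to the distance-only criterion.
#'
#' @param model a perceived `ttmd_complex`.
#' @param frame a `ttmd_frame`, or `NULL` for the reference coordinates.
#' @param cfg a [geometry_config()].
#' @return data frame with columns `residue` (residue key) and `class`.
#' @export
detect_interactions <- function(model, frame = NULL, cfg = geometry_config()) {
  if (!isTRUE(model$perceived)) stop("model features not perceived; call perceive_features() first")
  if (is.null(frame)) frame <- as_reference_frame(model)
  check_frame_congruent(model, frame)
  P <- frame$protein_xyz
  L <- frame$ligand_xyz
  cc <- model$cache
  res_of <- function(rows) model$protein$reskey[rows]
  out_res <- character(0); out_cls <- character(0)
  emit <- function(residues, class) {
    if (length(residues)) {
      out_res <<- c(out_res, residues)
      out_cls <<- c(out_cls, rep(class, length(residues)))
    }
  }

  # hydrophobic contacts: hydrophobic-hydrophobic heavy-atom pairs
  if (length(cc$p_hydro) && length(cc$l_hydro)) {
    D <- pair_dist(P[cc$p_hydro, , drop = FALSE], L[cc$l_hydro, , drop = FALSE])
    hit <- which(D <= cfg$hydrophobic_dmax, arr.ind = TRUE)
    emit(res_of(cc$p_hydro[hit[, 1]]), "hydrophobic")
  }

  # hydrogen bonds, protein as donor
  if (length(cc$p_donor) && length(cc$l_acc)) {
    D <- pair_dist(P[cc$p_donor, , drop = FALSE], L[cc$l_acc, , drop = FALSE])
    hit <- which(D <= cfg$hbond_dmax, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      di <- hit[k, 1]; aj <- cc$l_acc[hit[k, 2]]
      hrows <- cc$p_donor_h[[di]]
      ok <- if (length(hrows) == 0) {
        if (isTRUE(cfg$warn_missing_h))
          warning("donor without recorded hydrogen: distance-only hydrogen-bond criterion",
                  call. = FALSE)
        TRUE
      } else {
        any(vapply(hrows, function(h)
          angle_at(P[h, ], P[cc$p_donor[di], ], L[aj, ]) >= cfg$hbond_angle_min, TRUE))
      }
      if (ok) emit(res_of(cc$p_donor[di]), "hbond_protein_donor")
    }
  }

  # hydrogen bonds, protein as acceptor
  if (length(cc$p_acc) && length(cc$l_donor)) {
    D <- pair_dist(L[cc$l_donor, , drop = FALSE], P[cc$p_acc, , drop = FALSE])
    hit <- which(D <= cfg$hbond_dmax, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      di <- hit[k, 1]; aj <- cc$p_acc[hit[k, 2]]
      hrows <- cc$l_donor_h[[di]]
      ok <- if (length(hrows) == 0) {
        if (isTRUE(cfg$warn_missing_h))
          warning("donor without recorded hydrogen: distance-only hydrogen-bond criterion",
                  call. = FALSE)
        TRUE
      } else {
        any(vapply(hrows, function(h)
          angle_at(L[h, ], L[cc$l_donor[di], ], P[aj, ]) >= cfg$hbond_angle_min, TRUE))
      }
      if (ok) emit(res_of(aj), "hbond_protein_acceptor")
    }
  }

  # salt bridges, classed by which side carries the protein charge
  if (length(cc$p_cat) && length(cc$l_ani)) {
    D <- pair_dist(P[cc$p_cat, , drop = FALSE], L[cc$l_ani, , drop = FALSE])
    hit <- which(D <= cfg$saltbridge_dmax, arr.ind = TRUE)
    emit(res_of(cc$p_cat[hit[, 1]]), "saltbridge_protein_positive")
  }
  if (length(cc$p_ani) && length(cc$l_cat)) {
    D <- pair_dist(P[cc$p_ani, , drop = FALSE], L[cc$l_cat, , drop = FALSE])
    hit <- which(D <= cfg$saltbridge_dmax, arr.ind = TRUE)
    emit(res_of(cc$p_ani[hit[, 1]]), "saltbridge_protein_negative")
  }

  # aromatic ring-ring interactions
  if (length(cc$p_rings) && length(cc$l_rings)) {
    for (pr in cc$p_rings) {
      gp <- ring_geometry(P[pr$rows, , drop = FALSE])
      for (lr in cc$l_rings) {
        gl <- ring_geometry(L[lr$rows, , drop = FALSE])
        d <- sqrt(sum((gp$centroid - gl$centroid)^2))
        if (d > cfg$ring_centroid_dmax) next
        ang <- acos(min(1, abs(sum(gp$normal * gl$normal)))) * 180 / pi
        if (ang <= cfg$face_angle_max) emit(pr$owner, "aromatic_face_to_face")
        else if (ang >= cfg$edge_angle_range[1] && ang <= cfg$edge_angle_range[2])
          emit(pr$owner, "aromatic_edge_to_face")
      }
    }
  }

  # ionic bonds with protein-bound metals
  if (length(cc$p_metal)) {
    lig_targets <- union(cc$l_ani, cc$l_acc)
    if (length(lig_targets)) {
      D <- pair_dist(P[cc$p_metal, , drop = FALSE], L[lig_targets, , drop = FALSE])
      hit <- which(D <= cfg$metal_dmax, arr.ind = TRUE)
      emit(res_of(cc$p_metal[hit[, 1]]), "metal_ionic")
    }
  }

  data.frame(residue = out_res, class = out_cls, stringsAsFactors = FALSE)
}

#' Encode interactions as the r x 8 integer fingerprint
#'
#' Slot layout: residue `i` (1-based position in `residue_order`) and
#' class `c` (0-based position in [interaction_classes()]) occupy element
#' `(i - 1) * 8 + c + 1`; the value is the number of detected instances.
#'
#' @param interactions data frame from [detect_interactions()].
#' @param residue_order the model's frozen residue ordering.
#' @param r number of protein residues (defaults to `length(residue_order)`).
#' @return object of class `ttmd_fingerprint`: an integer vector of length
#'   `r * 8` with attributes `residue_order` and `r`.
#' @export
build_fingerprint <- function(interactions, residue_order, r = length(residue_order)) {
  stopifnot(r == length(residue_order))
  counts <- integer(r * 8)
  if (nrow(interactions)) {
    ri <- match(interactions$residue, residue_order)
    if (anyNA(ri)) stop("unknown residue key: ",
                        paste(unique(interactions$residue[is.na(ri)]), collapse = ", "))
    ci <- match(interactions$class, interaction_classes())
    if (anyNA(ci)) stop("unknown interaction class")
    slot <- (ri - 1) * 8 + ci
    tab <- table(slot)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  structure(counts, residue_order = residue_order, r = r, class = "ttmd_fingerprint")
}

#' Cosine similarity of two count vectors
#'
#' `dot(a, b) / (|a| |b|)`; by convention 0 when either vector is all
#' zero (a fully dissociated ligand shares no feature with any reference).
#'
#' @param a,b numeric vectors of equal length.
#' @return a number in `[0, 1]` for non-negative vectors.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch: ", length(a), " vs ", length(b))
  na <- sqrt(sum(as.numeric(a)^2)); nb <- sqrt(sum(as.numeric(b)^2))
  if (na == 0 || nb == 0) return(0)
  sum(as.numeric(a) * as.numeric(b)) / (na * nb)
}

#' IFP_CS: fingerprint similarity score of a frame against the reference
#'
#' The cosine similarity between the reference and query fingerprints,
#' multiplied by -1 so that, like most scoring functions, more negative
#' means better: -1 is total convergence to the native binding mode, 0
#' means every reference interaction has been lost.
#'
#' @param reference,query `ttmd_fingerprint` objects over the same
#'   residue order (the reference must not be all zero).
#' @return a number in `[-1, 0]`.
#' @export
ifp_cs_score <- function(reference, query) {
  if (length(reference) != length(query)) stop("fingerprint length mismatch")
  ro_r <- attr(reference, "residue_order"); ro_q <- attr(query, "residue_order")
  if (!is.null(ro_r) && !is.null(ro_q) && !identical(ro_r, ro_q))
    stop("fingerprints computed over different residue orders")
  if (all(reference == 0)) stop("all-zero reference fingerprint (invalid native pose)")
  -cosine_similarity(reference, query)
}

#' Mean IFP_CS over the frames of one window
#' @param scores numeric vector (or list of frame-score records with an
#'   `ifp_cs` element) for one temperature window.
#' @return arithmetic mean of the per-frame scores.
#' @export
window_mean_ifpcs <- function(scores) {
  if (is.list(scores)) scores <- vapply(scores, function(s) s$ifp_cs, 0)
  if (length(scores) == 0) stop("empty window: no frame scores")
  mean(scores)
}
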