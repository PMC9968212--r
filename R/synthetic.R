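#' Declare a synthetic ligand with known native interactions
#'
#' The synthetic backend's ground truth: a set of native interactions
#' (one per declared class/residue pair), each with a characteristic
#' temperature above which it is lost. During toy dynamics each
#' interaction is intact in a frame with probability
#' `p_i(T) = 1 / (1 + exp((T - T_i) / sharpness))` - a logistic retention
#' curve in temperature, the simplest monotone model with a controllable
#' unbinding window.
#'
#' @param classes character vector of interaction classes
#'   (see [interaction_classes()]).
#' @param residues 1-based protein residue index hosting each interaction
#'   (distinct; defaults to `1:length(classes)`).
#' @param characteristic_temperatures one per interaction, K.
#' @param sharpness logistic width, K.
#' @param rebind_probability per-frame probability that a dissociated
#'   ligand restores a lost interaction.
#' @param seed integer seed controlling fixture geometry jitter.
#' @return object of class `ttmd_ligand_spec`.
#' @export
synthetic_ligand_spec <- function(classes, residues = seq_along(classes),
                                  characteristic_temperatures,
                                  sharpness = 5, rebind_probability = 0,
                                  seed = 1) {
  classes <- as.character(classes)
  bad <- setdiff(classes, interaction_classes())
  if (length(bad)) stop("unknown interaction class: ", paste(bad, collapse = ", "))
  if (length(classes) && length(characteristic_temperatures) != length(classes))
    stop("one characteristic temperature per interaction is required")
  if (length(residues) != length(classes)) stop("one residue index per interaction")
  if (anyDuplicated(residues)) stop("infeasible geometry packing: duplicated residue indices")
  if (sharpness <= 0) stop("sharpness must be > 0")
  if (rebind_probability < 0 || rebind_probability > 1)
    stop("rebind_probability must lie in [0, 1]")
  structure(list(classes = classes, residues = as.integer(residues),
                 characteristic_temperatures = as.numeric(characteristic_temperatures),
                 sharpness = sharpness, rebind_probability = rebind_probability,
                 seed = as.integer(seed)),
            class = "ttmd_ligand_spec")
}

# ---- geometry templates ------------------------------------------------
# Each interaction site occupies its own residue on a 25 A grid along x,
# with the ligand moiety placed strictly inside the detection thresholds
# (margin >= 0.3 A / 10 deg) and no undeclared interaction within
# threshold + 0.5 A (hydrogen-bond near-misses are excluded by >= 55 deg
# of angular margin where a distance margin is geometrically impossible).

site_backbone <- function(resname = "GLY") {
  data.frame(name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
             x = c(-1.2, 0, 1.3, 1.9), y = c(-0.8, 0, 0, 1.13), z = 0,
             resname = resname, stringsAsFactors = FALSE)
}

ring_coords <- function(centroid, radius, u, v, phase = 0) {
  th <- phase + seq(0, 300, by = 60) * pi / 180
  t(vapply(th, function(a) centroid + radius * (cos(a) * u + sin(a) * v), numeric(3)))
}

site_template <- function(class) {
  bb <- site_backbone()
  lig <- NULL; lig_bonds <- NULL
  prot_extra <- NULL
  deg10 <- 10 * pi / 180
  switch(class,
    hydrophobic = {
      bb$resname <- "LEU"
      prot_extra <- data.frame(
        name = c("CB", "CG", "CD1", "CD2"), element = "C",
        x = c(1.2, 2.6, 4.0, 2.9), y = c(1.0, 0.8, 0.0, 2.2), z = 0,
        resname = "LEU", stringsAsFactors = FALSE)
      lig <- data.frame(element = c("C", "C"), x = c(7.5, 9.0), y = 0, z = 0,
                        charge = 0L, stringsAsFactors = FALSE)
      lig_bonds <- data.frame(a = 1L, b = 2L, order = 1L, aromatic = FALSE)
    },
    aromatic_face_to_face = {
      bb$resname <- "PHE"
      ring <- ring_coords(c(4.5, 0, 0), 1.39, c(0, 1, 0), c(0, 0, 1))
      prot_extra <- data.frame(
        name = c("CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"), element = "C",
        x = c(3.2, ring[, 1]), y = c(0, ring[, 2]), z = c(2.0, ring[, 3]),
        resname = "PHE", stringsAsFactors = FALSE)
      lr <- ring_coords(c(8.5, 0, 0), 1.35, c(0, 1, 0), c(0, 0, 1))
      lig <- data.frame(element = c("N", "C", "N", "C", "N", "C"),
                        x = lr[, 1], y = lr[, 2], z = lr[, 3],
                        charge = 0L, stringsAsFactors = FALSE)
      lig_bonds <- data.frame(a = 1:6, b = c(2:6, 1), order = 4L, aromatic = TRUE)
    },
    aromatic_edge_to_face = {
      bb$resname <- "PHE"
      ring <- ring_coords(c(4.5, 0, 0), 1.39, c(0, 1, 0), c(0, 0, 1))
      prot_extra <- data.frame(
        name = c("CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"), element = "C",
        x = c(3.2, ring[, 1]), y = c(0, ring[, 2]), z = c(2.0, ring[, 3]),
        resname = "PHE", stringsAsFactors = FALSE)
      # ligand ring tilted 10 deg off perpendicular: inter-normal angle 80 deg
      u <- c(-cos(deg10), 0, sin(deg10)); v <- c(0, 1, 0)
      lr <- ring_coords(c(9.1, 0, 0), 1.35, u, v)
      lig <- data.frame(element = c("C", "N", "C", "N", "C", "N"),
                        x = lr[, 1], y = lr[, 2], z = lr[, 3],
                        charge = 0L, stringsAsFactors = FALSE)
      lig_bonds <- data.frame(a = 1:6, b = c(2:6, 1), order = 4L, aromatic = TRUE)
    },
    hbond_protein_donor = {
      bb$resname <- "SER"
      prot_extra <- data.frame(
        name = c("CB", "OG", "HG"), element = c("C", "O", "H"),
        x = c(2.7, 4.0, 4.96), y = c(0.7, 0, 0), z = 0,
        resname = "SER", stringsAsFactors = FALSE)
      lig <- data.frame(element = "O", x = 6.9, y = 0, z = 0, charge = 0L,
                        stringsAsFactors = FALSE)
      lig_bonds <- data.frame(a = integer(0), b = integer(0),
                              order = integer(0), aromatic = logical(0))
    },
    hbond_protein_acceptor = {
      o <- c(1.9, 1.13, 0); ca <- c(0, 0, 0)
      u <- (o - ca) / sqrt(sum((o - ca)^2))
      n_pos <- o + 2.9 * u
      h_pos <- n_pos - 1.0 * u
      lig <- data.frame(element = c("N", "H"),
                        x = c(n_pos[1], h_pos[1]), y = c(n_pos[2], h_pos[2]),
                        z = c(n_pos[3], h_pos[3]), charge = 0L,
                        stringsAsFactors = FALSE)
      lig_bonds <- data.frame(a = 1L, b = 2L, order = 1L, aromatic = FALSE)
    },
    saltbridge_protein_positive = {
      bb$resname <- "LYS"
      prot_extra <- data.frame(
        name = c("CB", "CG", "CD", "CE", "NZ", "HZ1", "HZ2", "HZ3"),
        element = c("C", "C", "C", "C", "N", "H", "H", "H"),
        x = c(1.2, 2.4, 3.0, 3.6, 4.0, 3.1, 3.1, 4.0),
        y = c(1.0, 0.4, 1.6, 0.6, 0.0, 0.5, -0.5, 0.0),
        z = c(0, 0, 0, 0, 0, 0, 0, 1.0),
        resname = "LYS", stringsAsFactors = FALSE)
      lig <- data.frame(element = "O", x = 7.7, y = 0, z = 0, charge = -1L,
                        stringsAsFactors = FALSE)
      lig_bonds <- data.frame(a = integer(0), b = integer(0),
                              order = integer(0), aromatic = logical(0))
    },
    saltbridge_protein_negative = {
      bb$resname <- "ASP"
      prot_extra <- data.frame(
        name = c("CB", "CG", "OD1", "OD2"), element = c("C", "C", "O", "O"),
        x = c(1.2, 2.8, 4.0, 3.0), y = c(1.0, 0.6, 0.0, 1.9), z = 0,
        resname = "ASP", stringsAsFactors = FALSE)
      lig <- data.frame(element = "N", x = 7.7, y = 0, z = 0, charge = 1L,
                        stringsAsFactors = FALSE)
      lig_bonds <- data.frame(a = integer(0), b = integer(0),
                              order = integer(0), aromatic = logical(0))
    },
    metal_ionic = {
      bb <- data.frame(name = "ZN", element = "ZN", x = 0, y = 0, z = 0,
                       resname = "ZN", stringsAsFactors = FALSE)
      lig <- data.frame(element = "O", x = 2.7, y = 0, z = 0, charge = -1L,
                        stringsAsFactors = FALSE)
      lig_bonds <- data.frame(a = integer(0), b = integer(0),
                              order = integer(0), aromatic = logical(0))
    },
    stop("no geometry template for class ", class)
  )
  list(protein = rbind(bb, prot_extra), ligand = lig, ligand_bonds = lig_bonds)
}

#' Build a fixture complex realising a synthetic ligand spec
#'
#' Places one interaction site per declared interaction on a 25 Angstrom
#' grid: the host residue carries the protein-side template for its
#' interaction class, every other residue is a plain glycine, and the
#' ligand is a multi-fragment probe molecule whose moieties realise each
#' declared interaction strictly inside the detection thresholds while no
#' undeclared interaction comes near any threshold. Deterministic given
#' the spec's seed (which drives a small sub-margin coordinate jitter).
#'
#' @param spec a [synthetic_ligand_spec()].
#' @param n_residues total protein residues (>= the largest referenced
#'   residue index; extra residues are glycines).
#' @return list with elements `model` (a perceived `ttmd_complex` carrying
#'   the synthetic templates), `reference_frame`, `spec`, and `declared`
#'   (the ground-truth residue/class table).
#' @export
make_fixture_complex <- function(spec, n_residues = NULL) {
  stopifnot(inherits(spec, "ttmd_ligand_spec"))
  n_int <- length(spec$classes)
  if (is.null(n_residues)) n_residues <- max(c(spec$residues, 2L))
  if (n_int && n_residues < max(spec$residues))
    stop("n_residues smaller than the largest referenced residue index")

  prot_list <- list(); lig_list <- list(); bond_list <- list()
  interactions <- list()
  lig_offset <- 0L
  for (i in seq_len(n_residues)) {
    g <- c((i - 1) * 25, 0, 0)
    k <- match(i, spec$residues)
    tpl <- if (!is.na(k)) site_template(spec$classes[k]) else list(protein = site_backbone())
    pr <- tpl$protein
    pr$x <- pr$x + g[1]; pr$y <- pr$y + g[2]; pr$z <- pr$z + g[3]
    pr$resno <- i
    prot_list[[i]] <- pr
    if (!is.na(k)) {
      lg <- tpl$ligand
      lg$x <- lg$x + g[1]; lg$y <- lg$y + g[2]; lg$z <- lg$z + g[3]
      bd <- tpl$ligand_bonds
      bd$a <- bd$a + lig_offset; bd$b <- bd$b + lig_offset
      interactions[[k]] <- list(class = spec$classes[k], residue = i,
                                lig_rows = lig_offset + seq_len(nrow(lg)))
      lig_offset <- lig_offset + nrow(lg)
      lig_list[[length(lig_list) + 1]] <- lg
      bond_list[[length(bond_list) + 1]] <- bd
    }
  }
  if (n_int == 0) {
    # inert probe far from the protein: parses, but has no native interactions
    lig_list[[1]] <- data.frame(element = "C", x = 0, y = 20, z = 0, charge = 0L,
                                stringsAsFactors = FALSE)
    bond_list[[1]] <- data.frame(a = integer(0), b = integer(0),
                                 order = integer(0), aromatic = logical(0))
  }

  prot <- do.call(rbind, prot_list)
  lig <- do.call(rbind, lig_list)
  bonds <- do.call(rbind, bond_list)

  # deterministic sub-margin jitter so distinct seeds give distinct geometry
  jit <- with_seed(derive_seed(spec$seed, 101L),
                   matrix(stats::runif(nrow(lig) * 3, -0.06, 0.06), ncol = 3))
  lig$x <- lig$x + jit[, 1]; lig$y <- lig$y + jit[, 2]; lig$z <- lig$z + jit[, 3]

  prot_df <- data.frame(
    serial = seq_len(nrow(prot)), name = prot$name, element = prot$element,
    x = prot$x, y = prot$y, z = prot$z,
    chain = "A", resno = prot$resno, insert = "", resname = prot$resname,
    is_h = prot$element == "H", is_metal = prot$element %in% METAL_ELEMENTS,
    stringsAsFactors = FALSE)
  prot_df$reskey <- residue_key(prot_df$chain, prot_df$resno, prot_df$insert,
                                prot_df$resname)
  prot_df$heavy <- NA_integer_
  for (h in which(prot_df$is_h)) {
    same <- which(!prot_df$is_h & prot_df$reskey == prot_df$reskey[h])
    d <- pair_dist(as.matrix(prot_df[h, c("x", "y", "z")]),
                   as.matrix(prot_df[same, c("x", "y", "z")]))
    hit <- same[d <= 1.2]
    if (length(hit)) prot_df$heavy[h] <- prot_df$serial[hit[which.min(d[d <= 1.2])]]
  }

  lig_df <- data.frame(
    serial = seq_len(nrow(lig)),
    name = paste0(lig$element, seq_len(nrow(lig))),
    element = lig$element, x = lig$x, y = lig$y, z = lig$z,
    charge = lig$charge, is_h = lig$element == "H",
    stringsAsFactors = FALSE)
  lig2 <- finish_ligand(lig_df, bonds)

  model <- structure(list(
    protein = prot_df, ligand = lig2$atoms, ligand_bonds = bonds,
    rings = list(), residue_order = unique(prot_df$reskey),
    r = length(unique(prot_df$reskey)), perceived = FALSE
  ), class = "ttmd_complex")
  model <- perceive_features(model)

  model$synthetic <- list(
    interactions = interactions,
    lig_template = as.matrix(model$ligand[, c("x", "y", "z")]),
    prot_xyz = as.matrix(model$protein[, c("x", "y", "z")]),
    lost_shift = c(0, 8, 0),
    spec = spec
  )
  declared <- if (n_int) data.frame(
    residue = model$residue_order[spec$residues],
    class = spec$classes, stringsAsFactors = FALSE
  ) else data.frame(residue = character(0), class = character(0))

  list(model = model, reference_frame = as_reference_frame(model),
       spec = spec, declared = declared)
}

#' Toy stochastic dynamics backend for a fixture complex
#'
#' Returns a function satisfying the dynamics backend contract
#' (`(state, temperature, duration_ns, stride_ps, seed) -> list(frames,
#' end_state)`). Per frame, each native interaction is independently
#' intact with its logistic retention probability; an intact moiety keeps
#' its template geometry up to a 0.2 A jitter, a lost moiety is displaced
#' well beyond every detection threshold. Once all interactions have been
#' absent for one full window the end state marks the ligand dissociated:
#' later frames stay interaction-free unless `rebind_probability > 0`.
#'
#' @param fixture result of [make_fixture_complex()].
#' @return backend function for [run_titration()].
#' @export
synth_backend <- function(fixture) {
  syn <- fixture$model$synthetic
  spec <- syn$spec
  n_int <- length(syn$interactions)
  function(state, temperature, duration, stride, seed) {
    n_frames <- max(1L, as.integer(round(duration * 1000 / stride)))
    dissociated <- isTRUE(state$dissociated)
    t0 <- state$time %||% 0
    frames <- vector("list", n_frames)
    any_intact_in_window <- FALSE
    with_seed(seed, {
      for (j in seq_len(n_frames)) {
        xyz <- syn$lig_template
        intact <- logical(n_int)
        if (n_int) {
          p <- 1 / (1 + exp((temperature - spec$characteristic_temperatures) / spec$sharpness))
          intact <- if (dissociated) stats::runif(n_int) < spec$rebind_probability
                    else stats::runif(n_int) < p
          for (k in seq_len(n_int)) {
            rows <- syn$interactions[[k]]$lig_rows
            jitter <- matrix(stats::runif(length(rows) * 3, -0.06, 0.06), ncol = 3)
            if (intact[k]) {
              xyz[rows, ] <- xyz[rows, ] + jitter
            } else {
              xyz[rows, ] <- xyz[rows, ] +
                matrix(syn$lost_shift, nrow = length(rows), ncol = 3, byrow = TRUE) + jitter
            }
          }
        }
        if (any(intact)) any_intact_in_window <- TRUE
        frames[[j]] <- new_frame(syn$prot_xyz, xyz, index = j,
                                 time = t0 + j * stride, temperature = temperature)
      }
    })
    if (!dissociated && !any_intact_in_window) dissociated <- TRUE
    list(frames = frames,
         end_state = list(dissociated = dissociated,
                          time = t0 + n_frames * stride))
  }
}

#' Generate a synthetic multi-pose set with known stability order
#'
#' Mirrors a docking-pose discrimination experiment: `n_poses` poses of
#' one ligand share the protein and ligand topology but differ in the
#' characteristic temperatures of their native interactions, so the true
#' stability ranking (by median characteristic temperature, most stable
#' first) is known by construction.
#'
#' @param n_poses number of poses (>= 2).
#' @param temperatures per-pose base characteristic temperature, K
#'   (default evenly spread from 320 to 440).
#' @param classes interaction classes shared by all poses.
#' @param stagger_K deterministic within-pose spread of the per-interaction
#'   characteristic temperatures around the pose base value, K.
#' @param sharpness,rebind_probability passed to each pose's spec.
#' @param seed master seed; each pose derives its own geometry seed.
#' @return object of class `ttmd_pose_set` with `poses` (each with `id`,
#'   `spec`, `fixture`) and `true_stability_order` (pose ids, most stable
#'   first).
#' @export
make_pose_set <- function(n_poses = 5,
                          temperatures = seq(320, 440, length.out = n_poses),
                          classes = c("hydrophobic", "aromatic_face_to_face",
                                      "hbond_protein_donor",
                                      "hbond_protein_acceptor",
                                      "saltbridge_protein_positive"),
                          stagger_K = 4, sharpness = 5,
                          rebind_probability = 0, seed = 1) {
  if (n_poses < 2) stop("n_poses must be >= 2")
  if (length(temperatures) != n_poses) stop("one base temperature per pose")
  if (length(unique(temperatures)) == 1)
    warning("degenerate temperature spread: true stability order is undefined")
  n_int <- length(classes)
  stag <- if (n_int > 1) seq(-stagger_K, stagger_K, length.out = n_int) else 0
  poses <- lapply(seq_len(n_poses), function(k) {
    spec <- synthetic_ligand_spec(
      classes = classes, residues = seq_len(n_int),
      characteristic_temperatures = temperatures[k] + stag,
      sharpness = sharpness, rebind_probability = rebind_probability,
      seed = derive_seed(seed, k))
    list(id = paste0("pose", k), spec = spec,
         fixture = make_fixture_complex(spec, n_residues = n_int + 1L))
  })
  ids <- vapply(poses, `[[`, "", "id")
  structure(list(poses = poses,
                 true_stability_order = ids[order(-temperatures, ids)],
                 temperatures = temperatures, classes = classes, seed = seed),
            class = "ttmd_pose_set")
}

#' Write fixture input files (PDB + SDF + YAML spec)
#'
#' Exercises the real file I/O path: the written complex re-parses with
#' [parse_complex()] to the same residue order, atom counts and feature
#' flags.
#'
#' @param fixture result of [make_fixture_complex()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of paths.
#' @export
write_fixture_files <- function(fixture, dir, prefix = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ppath <- file.path(dir, paste0(prefix, "_protein.pdb"))
  lpath <- file.path(dir, paste0(prefix, "_ligand.sdf"))
  spath <- file.path(dir, paste0(prefix, "_spec.yaml"))
  write_complex(fixture$model, ppath, lpath)
  yaml::write_yaml(unclass(fixture$spec), spath)
  c(protein = ppath, ligand = lpath, spec = spath)
}

#' Write frames to a DCD trajectory file
#'
#' Minimal single-precision CHARMM/X-PLOR-style DCD writer used for
#' synthetic trajectories; files read back with `bio3d::read.dcd`.
#' Frames hold protein atoms followed by ligand atoms, in model order.
#'
#' @param frames list of `ttmd_frame`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_dcd <- function(frames, file) {
  if (length(frames) == 0) stop("no frames to write")
  natom <- nrow(frames[[1]]$protein_xyz) + nrow(frames[[1]]$ligand_xyz)
  con <- file(file, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: length marker, payload, length marker
    tmp <- raw(0)
    tcon <- rawConnection(tmp, "wb")
    writer(tcon)
    payload <- rawConnectionValue(tcon)
    close(tcon)
    writeBin(length(payload), con, size = 4)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- length(frames)   # frames in file
  icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- length(frames)
  rec(function(c_) { writeChar("CORD", c_, nchars = 4, eos = NULL)
                     writeBin(icntrl, c_, size = 4) })
  rec(function(c_) { writeBin(1L, c_, size = 4)
                     writeChar(formatC("ttmd synthetic trajectory", width = -80), c_,
                               nchars = 80, eos = NULL) })
  rec(function(c_) writeBin(as.integer(natom), c_, size = 4))
  for (fr in frames) {
    xyz <- rbind(fr$protein_xyz, fr$ligand_xyz)
    for (d in 1:3) rec(function(c_) writeBin(as.numeric(xyz[, d]), c_, size = 4))
  }
  invisible(file)
}
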