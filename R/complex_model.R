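# metals recognised as protein-bound ions (by element symbol)
METAL_ELEMENTS <- c("ZN", "MG", "MN", "FE", "CU", "NI", "CO", "NA", "K", "CA", "CD")
HALOGENS <- c("F", "CL", "BR", "I")

residue_key <- function(chain, resno, insert, resname) {
  insert[is.na(insert)] <- ""
  chain[is.na(chain)] <- ""
  paste(chain, resno, insert, resname, sep = "|")
}

guess_element <- function(name, elesy = NA) {
  ele <- toupper(trimws(as.character(elesy)))
  bad <- is.na(ele) | ele == ""
  if (any(bad)) {
    nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", trimws(name[bad]))))
    # two-letter elements only when unambiguous (metals, halogens)
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    ele[bad] <- ifelse(two %in% c(METAL_ELEMENTS, "CL", "BR"), two, one)
  }
  ele
}

#' Parse a protein-ligand complex
#'
#' Reads a protein structure (PDB) and a ligand with explicit bonds and
#' formal charges (SDF V2000 or MOL2) into a single complex model. The
#' protein residue ordering is frozen in file order and defines the row
#' layout of every interaction fingerprint computed from this model.
#' Alternate locations keep the highest-occupancy copy; hydrogens are
#' attached to their heavy atom by bond (ligand) or by a 1.2 A distance
#' criterion (protein). Metal ions (HETATM, recognised by element) are
#' retained as single-atom protein residues so metal coordination has a
#' fingerprint slot.
#'
#' @param protein_file path to a PDB file (wwPDB v3.3 ATOM/HETATM records).
#' @param ligand_file path to an SDF (V2000) or MOL2 file.
#' @return an object of class `ttmd_complex` with elements `protein`,
#'   `ligand` (atom data frames), `ligand_bonds`, `residue_order`, `r`.
#'   Call [perceive_features()] before interaction detection.
#' @export
parse_complex <- function(protein_file, ligand_file) {
  if (!file.exists(protein_file)) stop("protein file not found: ", protein_file)
  if (!file.exists(ligand_file)) stop("ligand file not found: ", ligand_file)

  pdb <- bio3d::read.pdb(protein_file, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$element <- guess_element(at$elety, at$elesy)

  is_metal <- at$type == "HETATM" & at$element %in% METAL_ELEMENTS &
    !(at$resid %in% bio3d::aa.table$aa3)
  keep <- at$type == "ATOM" | is_metal
  at <- at[keep, , drop = FALSE]
  is_metal <- is_metal[keep]
  if (nrow(at) == 0) stop("zero protein residues in ", protein_file)

  # alternate locations: highest occupancy per (chain, resno, insert, name)
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(match(key, unique(key)), -occ)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), , drop = FALSE]
    at <- at[order(match(at$eleno, pdb$atom$eleno)), , drop = FALSE]
    is_metal <- at$type == "HETATM" & at$element %in% METAL_ELEMENTS &
      !(at$resid %in% bio3d::aa.table$aa3)
  }

  if (anyDuplicated(at$eleno)) stop("duplicate atom serials in protein file")

  prot <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = at$element,
    x = at$x, y = at$y, z = at$z,
    chain = at$chain, resno = at$resno, insert = at$insert, resname = at$resid,
    is_h = at$element == "H", is_metal = is_metal,
    stringsAsFactors = FALSE
  )
  prot$reskey <- residue_key(prot$chain, prot$resno, prot$insert, prot$resname)

  residue_order <- unique(prot$reskey)
  if (length(residue_order) == 0) stop("zero protein residues")

  # attach hydrogens to nearest heavy atom within 1.2 A (same residue first)
  prot$heavy <- NA_integer_
  hidx <- which(prot$is_h)
  if (length(hidx)) {
    heavy_idx <- which(!prot$is_h)
    D <- pair_dist(as.matrix(prot[hidx, c("x", "y", "z")]),
                   as.matrix(prot[heavy_idx, c("x", "y", "z")]))
    for (k in seq_along(hidx)) {
      same <- prot$reskey[heavy_idx] == prot$reskey[hidx[k]]
      cand <- which(D[k, ] <= 1.2 & same)
      if (!length(cand)) cand <- which(D[k, ] <= 1.2)
      if (length(cand)) prot$heavy[hidx[k]] <- prot$serial[heavy_idx[cand[which.min(D[k, cand])]]]
    }
  }

  lig <- read_ligand(ligand_file)
  if (sum(!lig$atoms$is_h) == 0) stop("zero ligand heavy atoms in ", ligand_file)
  if (anyDuplicated(lig$atoms$serial)) stop("duplicate atom serials in ligand file")

  structure(list(
    protein = prot,
    ligand = lig$atoms,
    ligand_bonds = lig$bonds,
    rings = list(),
    residue_order = residue_order,
    r = length(residue_order),
    perceived = FALSE
  ), class = "ttmd_complex")
}

read_ligand <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("sdf", "sd", "mol")) read_ligand_sdf(file)
  else if (ext == "mol2") read_ligand_mol2(file)
  else stop("unsupported ligand format: ", ext, " (use SDF or MOL2)")
}

read_ligand_sdf <- function(file) {
  lines <- readLines(file, warn = FALSE)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(file))
  sdf <- sdfs[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(ab)) || ncol(ab) < 3 || !all(grepl("_", rownames(ab)))) {
    # ChemmineR mishandles molecules with an empty bond block; read the
    # fixed-width V2000 blocks directly in that case
    na <- as.integer(substr(lines[4], 1, 3))
    nb <- as.integer(substr(lines[4], 4, 6))
    at <- lines[4 + seq_len(na)]
    ab <- cbind(as.numeric(substr(at, 1, 10)), as.numeric(substr(at, 11, 20)),
                as.numeric(substr(at, 21, 30)), 0, as.integer(substr(at, 37, 39)))
    rownames(ab) <- paste(toupper(trimws(substr(at, 32, 34))), seq_len(na), sep = "_")
    bb <- if (nb > 0) {
      bt <- lines[4 + na + seq_len(nb)]
      cbind(C1 = as.integer(substr(bt, 1, 3)), C2 = as.integer(substr(bt, 4, 6)),
            C3 = as.integer(substr(bt, 7, 9)))
    } else NULL
  }
  element <- toupper(sub("_.*$", "", rownames(ab)))
  n <- nrow(ab)
  charge <- integer(n)
  # old-style atom-block charge codes (column 5): 1..3 = +3..+1, 5..7 = -1..-3
  if (ncol(ab) >= 5) {
    code <- ab[, 5]
    charge <- ifelse(code %in% 1:3, 4L - as.integer(code),
              ifelse(code %in% 5:7, 4L - as.integer(code), 0L))
  }
  # M  CHG records override (ChemmineR does not surface them)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    v <- scan(text = substr(ln, 7, nchar(ln)), quiet = TRUE)
    if (length(v) >= 3) {
      np <- v[1]
      for (p in seq_len(np)) {
        i <- v[2 * p]; q <- v[2 * p + 1]
        if (!is.na(i) && i >= 1 && i <= n) charge[i] <- as.integer(q)
      }
    }
    break  # first molecule only
  }
  atoms <- data.frame(
    serial = seq_len(n),
    name = paste0(element, seq_len(n)),
    element = element,
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    charge = charge, is_h = element == "H",
    stringsAsFactors = FALSE
  )
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    data.frame(a = integer(0), b = integer(0), order = integer(0), aromatic = logical(0))
  } else {
    data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]), aromatic = as.integer(bb[, 3]) == 4L)
  }
  finish_ligand(atoms, bonds)
}

read_ligand_mol2 <- function(file) {
  mol <- bio3d::read.mol2(file)
  a <- mol$atom
  sybyl <- as.character(a$elety)
  element <- toupper(sub("\\..*$", "", sybyl))
  charge <- integer(nrow(a))
  charge[sybyl == "N.4"] <- 1L
  charge[sybyl == "O.co2"] <- -1L
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = as.character(a$elena),
    element = element,
    x = a$x, y = a$y, z = a$z,
    charge = charge, is_h = element == "H",
    stringsAsFactors = FALSE
  )
  b <- mol$bond
  bonds <- data.frame(a = as.integer(b$origin), b = as.integer(b$target),
                      order = suppressWarnings(as.integer(b$type)),
                      aromatic = b$type == "ar")
  bonds$order[is.na(bonds$order)] <- 1L
  finish_ligand(atoms, bonds)
}

finish_ligand <- function(atoms, bonds) {
  atoms$heavy <- NA_integer_
  if (nrow(bonds)) {
    for (k in which(atoms$is_h)) {
      nb <- c(bonds$b[bonds$a == atoms$serial[k]], bonds$a[bonds$b == atoms$serial[k]])
      nb <- nb[!atoms$is_h[match(nb, atoms$serial)]]
      if (length(nb)) atoms$heavy[k] <- nb[1]
    }
  }
  list(atoms = atoms, bonds = bonds)
}

#' Construct a trajectory frame
#'
#' @param protein_xyz,ligand_xyz coordinate matrices (n x 3, Angstrom)
#'   congruent with the model's atom tables (hydrogens included).
#' @param index frame index within its window.
#' @param time time in ps.
#' @param temperature set temperature of the window, K.
#' @return object of class `ttmd_frame`.
#' @export
new_frame <- function(protein_xyz, ligand_xyz, index = 1L, time = 0, temperature = 300) {
  stopifnot(ncol(protein_xyz) == 3, ncol(ligand_xyz) == 3, time >= 0)
  if (!all(is.finite(protein_xyz)) || !all(is.finite(ligand_xyz)))
    stop("non-finite coordinates in frame")
  dimnames(protein_xyz) <- NULL
  dimnames(ligand_xyz) <- NULL
  structure(list(index = as.integer(index), time = time, temperature = temperature,
                 protein_xyz = protein_xyz, ligand_xyz = ligand_xyz),
            class = "ttmd_frame")
}

#' Reference frame holding the model's own coordinates
#' @param model a `ttmd_complex`.
#' @param temperature set temperature tag, K.
#' @return a `ttmd_frame`.
#' @export
as_reference_frame <- function(model, temperature = 300) {
  new_frame(as.matrix(model$protein[, c("x", "y", "z")]),
            as.matrix(model$ligand[, c("x", "y", "z")]),
            index = 0L, time = 0, temperature = temperature)
}

check_frame_congruent <- function(model, frame) {
  if (nrow(frame$protein_xyz) != nrow(model$protein) ||
      nrow(frame$ligand_xyz) != nrow(model$ligand))
    stop("frame coordinate arrays do not match the complex model atom counts")
  invisible(TRUE)
}

#' Load trajectory frames from a DCD file
#'
#' Frames are expected to hold the model's protein atoms followed by its
#' ligand atoms, in model order (the layout written by the synthetic
#' backend and the convention for externally produced trajectories).
#'
#' @param model a `ttmd_complex`.
#' @param trajectory path to a CHARMM/NAMD-style DCD file.
#' @param window_metadata data frame with columns `temperature` (K) and
#'   `n_frames` assigning consecutive frames to temperature windows, or a
#'   single temperature applied to all frames.
#' @param stride_ps time between saved frames, ps.
#' @return list of `ttmd_frame`, times ascending.
#' @export
load_trajectory <- function(model, trajectory, window_metadata, stride_ps = 100) {
  xyz <- bio3d::read.dcd(trajectory, verbose = FALSE)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  if (nf == 0) stop("empty trajectory: ", trajectory)
  np <- nrow(model$protein); nl <- nrow(model$ligand)
  if (ncol(xyz) != 3 * (np + nl))
    stop("atom-count mismatch: trajectory has ", ncol(xyz) / 3,
         " atoms, model expects ", np + nl)
  temps <- if (is.data.frame(window_metadata)) {
    rep(window_metadata$temperature, window_metadata$n_frames)
  } else rep(window_metadata[1], nf)
  if (length(temps) < nf) stop("window metadata covers fewer frames than trajectory")
  lapply(seq_len(nf), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    new_frame(m[seq_len(np), , drop = FALSE], m[np + seq_len(nl), , drop = FALSE],
              index = i, time = (i - 1) * stride_ps, temperature = temps[i])
  })
}

#' Write the complex to PDB (protein) and SDF (ligand) files
#'
#' Fixture writer: emits the protein (metal ions as HETATM) and the ligand
#' with its bond and formal-charge blocks, so a written complex re-parses
#' to the same model.
#'
#' @param model a `ttmd_complex`.
#' @param protein_file,ligand_file output paths (.pdb and .sdf).
#' @return invisibly, the two paths.
#' @export
write_complex <- function(model, protein_file, ligand_file) {
  p <- model$protein
  bio3d::write.pdb(file = protein_file,
                   xyz = as.numeric(t(as.matrix(p[, c("x", "y", "z")]))),
                   type = ifelse(p$is_metal, "HETATM", "ATOM"),
                   resno = p$resno, resid = p$resname, eleno = p$serial,
                   elety = p$name, chain = p$chain,
                   insert = ifelse(p$insert == "", NA, p$insert),
                   elesy = p$element)
  write_ligand_sdf(model$ligand, model$ligand_bonds, ligand_file)
  invisible(c(protein_file, ligand_file))
}

write_ligand_sdf <- function(atoms, bonds, file) {
  n <- nrow(atoms); nb <- nrow(bonds)
  lines <- c("ttmd ligand", "  ttmd", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  el <- paste0(toupper(substr(atoms$element, 1, 1)),
               tolower(substr(atoms$element, 2, 2)))
  lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            atoms$x, atoms$y, atoms$z, el))
  if (nb) lines <- c(lines, sprintf("%3d%3d%3d  0", bonds$a, bonds$b,
                                    ifelse(bonds$aromatic, 4L, bonds$order)))
  chg <- which(atoms$charge != 0)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0(sprintf("M  CHG%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, atoms$charge[grp]), collapse = "")))
    }
  }
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, file)
  invisible(file)
}

#' @export
print.ttmd_complex <- function(x, ...) {
  cat("ttmd complex model:", x$r, "protein residues,",
      sum(!x$protein$is_h), "protein heavy atoms,",
      sum(!x$ligand$is_h), "ligand heavy atoms,",
      length(x$rings), "aromatic rings",
      if (x$perceived) "(features perceived)" else "(not yet perceived)", "\n")
  invisible(x)
}
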