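#' Default feature-perception rule table
#'
#' Protein typing is a fixed per-residue-name lookup for the 20 standard
#' amino acids at pH 7.4: Lys/Arg sidechains cationic, Asp/Glu anionic,
#' His neutral by default; backbone N is a donor (except proline) and
#' backbone O an acceptor. Hydrophobic protein atoms are the sidechain
#' carbons bonded only to carbon/hydrogen. Aromatic protein rings are the
#' canonical ring atoms of His/Phe/Tyr/Trp. Ligand typing is read from
#' the input file's bond and formal-charge blocks, never re-perceived.
#'
#' @return a list of lookup tables consumed by [perceive_features()].
#' @export
perception_rules <- function() {
  list(
    backbone_donor = "N",
    backbone_acceptor = c("O", "OXT"),
    no_backbone_donor_res = "PRO",
    cationic = list(LYS = "NZ", ARG = c("NE", "NH1", "NH2")),
    anionic = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
    sidechain_donor = list(
      LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = "NE2", SER = "OG",
      THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2", TRP = "NE1", CYS = "SG"),
    sidechain_acceptor = list(
      ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = "ND1", SER = "OG",
      THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1", MET = "SD"),
    # sidechain carbons whose bonded neighbours are all C/H
    hydrophobic = list(
      ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
      ILE = c("CB", "CG1", "CG2", "CD1"), PRO = c("CB", "CG"), MET = "CB",
      PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
      TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
      TRP = c("CB", "CG", "CD2", "CE3", "CZ3", "CH2", "CZ2"),
      LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
      GLU = c("CB", "CG"), GLN = c("CB", "CG"),
      ASP = "CB", ASN = "CB", HIS = "CB", THR = "CG2"),
    rings = list(
      HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
      PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
      TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
      TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                 c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2")))
  )
}

#' Perceive interaction features on a parsed complex
#'
#' Annotates every atom with its interaction roles (hydrophobic, hydrogen
#' bond donor/acceptor, formal charge class, metal) and detects aromatic
#' rings: protein rings from the canonical His/Phe/Tyr/Trp ring atoms,
#' ligand rings as 5-6-membered cycles of bonds flagged aromatic in the
#' input file. Deterministic and independent of atom input order for a
#' fixed `residue_order`.
#'
#' @param model a `ttmd_complex` from [parse_complex()].
#' @param rules rule table, see [perception_rules()].
#' @return the annotated `ttmd_complex` (with `perceived = TRUE`).
#' @export
perceive_features <- function(model, rules = perception_rules()) {
  stopifnot(inherits(model, "ttmd_complex"))
  p <- model$protein
  n <- nrow(p)
  lookup <- function(tab, resname, name) {
    hit <- tab[[resname]]
    !is.null(hit) && name %in% hit
  }
  p$charge_class <- "neutral"
  p$is_hydrophobic <- FALSE
  p$is_hbond_donor_heavy <- FALSE
  p$is_hbond_acceptor <- FALSE
  for (i in seq_len(n)) {
    if (p$is_h[i] || p$is_metal[i]) next
    rn <- p$resname[i]; nm <- p$name[i]
    if (lookup(rules$cationic, rn, nm)) p$charge_class[i] <- "cationic"
    if (lookup(rules$anionic, rn, nm)) p$charge_class[i] <- "anionic"
    if (lookup(rules$hydrophobic, rn, nm)) p$is_hydrophobic[i] <- TRUE
    if ((nm %in% rules$backbone_donor && !(rn %in% rules$no_backbone_donor_res)) ||
        lookup(rules$sidechain_donor, rn, nm)) p$is_hbond_donor_heavy[i] <- TRUE
    if (nm %in% rules$backbone_acceptor || lookup(rules$sidechain_acceptor, rn, nm))
      p$is_hbond_acceptor[i] <- TRUE
  }
  # a metal atom is neither donor nor acceptor nor charged for fingerprint purposes
  p$is_hbond_donor_heavy[p$is_metal] <- FALSE
  p$is_hbond_acceptor[p$is_metal] <- FALSE
  p$charge_class[p$is_metal] <- "neutral"

  l <- model$ligand
  bonds <- model$ligand_bonds
  if (any(l$element == "" | is.na(l$element))) stop("ligand atom with no element")
  deg <- integer(nrow(l))
  nbr_elements <- vector("list", nrow(l))
  if (nrow(bonds)) {
    for (i in seq_len(nrow(l))) {
      nb <- c(bonds$b[bonds$a == l$serial[i]], bonds$a[bonds$b == l$serial[i]])
      rows <- match(nb, l$serial)
      deg[i] <- length(rows)
      nbr_elements[[i]] <- l$element[rows]
    }
  }
  n_h <- vapply(seq_len(nrow(l)), function(i) sum(nbr_elements[[i]] == "H"), 0L)
  l$charge_class <- ifelse(l$charge > 0, "cationic", ifelse(l$charge < 0, "anionic", "neutral"))
  l$is_hydrophobic <- !l$is_h & l$element %in% c("C", HALOGENS) &
    vapply(seq_len(nrow(l)), function(i)
      all(nbr_elements[[i]] %in% c("C", HALOGENS, "H")), TRUE)
  l$is_hbond_donor_heavy <- !l$is_h & l$element %in% c("N", "O", "S") & n_h > 0
  l$is_hbond_acceptor <- !l$is_h & l$charge_class != "cationic" &
    (l$element == "O" | (l$element == "N" & deg < 4))
  l$is_metal <- FALSE

  rings <- c(protein_rings(p, rules), ligand_rings(l, bonds))
  # validate geometry at model coordinates
  for (rg in rings) {
    xyz <- if (rg$side == "protein") as.matrix(p[rg$rows, c("x", "y", "z")])
           else as.matrix(l[rg$rows, c("x", "y", "z")])
    ring_geometry(xyz)  # errors on collinear atoms
  }

  model$protein <- p
  model$ligand <- l
  model$rings <- rings
  model$perceived <- TRUE
  model$cache <- build_feature_cache(model)
  model
}

protein_rings <- function(p, rules) {
  out <- list()
  for (key in unique(p$reskey)) {
    rows_res <- which(p$reskey == key & !p$is_h)
    rn <- p$resname[rows_res[1]]
    defs <- rules$rings[[rn]]
    if (is.null(defs)) next
    for (def in defs) {
      rows <- rows_res[match(def, p$name[rows_res])]
      if (anyNA(rows)) next
      out[[length(out) + 1]] <- list(owner = key, side = "protein",
                                     rows = rows, serials = p$serial[rows])
    }
  }
  out
}

ligand_rings <- function(l, bonds) {
  ab <- bonds[bonds$aromatic, , drop = FALSE]
  if (nrow(ab) == 0) return(list())
  serials <- sort(unique(c(ab$a, ab$b)))
  adj <- lapply(serials, function(s) unique(c(ab$b[ab$a == s], ab$a[ab$b == s])))
  names(adj) <- as.character(serials)
  cycles <- list()
  seen <- character(0)
  # enumerate simple cycles of length 5 or 6 in the aromatic-bond subgraph
  walk <- function(path) {
    last <- path[length(path)]
    for (nxt in adj[[as.character(last)]]) {
      if (nxt == path[1] && length(path) >= 5) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1]] <<- path
        }
      } else if (!(nxt %in% path) && length(path) < 6 && nxt > path[1]) {
        walk(c(path, nxt))
      }
    }
  }
  for (s in serials) walk(s)
  lapply(cycles, function(cy) {
    rows <- match(cy, l$serial)
    list(owner = "ligand", side = "ligand", rows = rows, serials = cy)
  })
}

build_feature_cache <- function(model) {
  p <- model$protein; l <- model$ligand
  res_idx <- match(p$reskey, model$residue_order)
  donor_h <- function(df, donors) {
    lapply(donors, function(i) which(df$is_h & !is.na(df$heavy) & df$heavy == df$serial[i]))
  }
  pd <- which(p$is_hbond_donor_heavy & !p$is_h)
  ld <- which(l$is_hbond_donor_heavy & !l$is_h)
  list(
    res_idx = res_idx,
    p_hydro = which(p$is_hydrophobic & !p$is_h),
    p_donor = pd, p_donor_h = donor_h(p, pd),
    p_acc = which(p$is_hbond_acceptor & !p$is_h),
    p_cat = which(p$charge_class == "cationic" & !p$is_h),
    p_ani = which(p$charge_class == "anionic" & !p$is_h),
    p_metal = which(p$is_metal),
    l_hydro = which(l$is_hydrophobic & !l$is_h),
    l_donor = ld, l_donor_h = donor_h(l, ld),
    l_acc = which(l$is_hbond_acceptor & !l$is_h),
    l_cat = which(l$charge_class == "cationic" & !l$is_h),
    l_ani = which(l$charge_class == "anionic" & !l$is_h),
    l_heavy = which(!l$is_h),
    p_heavy = which(!p$is_h),
    p_rings = Filter(function(r) r$side == "protein", model$rings),
    l_rings = Filter(function(r) r$side == "ligand", model$rings)
  )
}
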