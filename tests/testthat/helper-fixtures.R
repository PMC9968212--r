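# in-code fixture builders shared across test files

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, elem = substr(name, 1, 1), record = "ATOM",
                          alt = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, resname, chain, resno,
          x, y, z, occ, 0, elem)
}

# n-residue glycine chain along x, 5 A apart
write_gly_chain_pdb <- function(path, n = 3, chains = "A", serial0 = 0) {
  lines <- character(0)
  serial <- serial0
  for (ch in chains) {
    for (i in seq_len(n)) {
      g <- (i - 1) * 5
      for (a in list(c("N", -1.2, -0.8), c("CA", 0, 0), c("C", 1.3, 0), c("O", 1.9, 1.13))) {
        serial <- serial + 1
        lines <- c(lines, pdb_atom_line(serial, a[[1]], "GLY", ch, i,
                                        g + as.numeric(a[[2]]), as.numeric(a[[3]]), 0))
      }
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

write_ethanol_sdf <- function(path) {
  writeLines(c(
    "ethanol", "  ttmd", "",
    "  4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.2000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.1600    1.1500    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0", "  3  4  1  0",
    "M  END", "$$$$"), path)
  path
}

write_benzene_sdf <- function(path) {
  th <- seq(0, 300, by = 60) * pi / 180
  atoms <- sprintf("%10.4f%10.4f%10.4f C   0  0  0  0  0  0  0  0  0  0  0  0",
                   1.39 * cos(th), 1.39 * sin(th), 0)
  bonds <- sprintf("%3d%3d  4  0", 1:6, c(2:6, 1))
  writeLines(c("benzene", "  ttmd", "",
               "  6  6  0  0  0  0  0  0  0  0999 V2000", atoms, bonds,
               "M  END", "$$$$"), path)
  path
}

# standard multi-class spec used in several tests
demo_spec <- function(temps = rep(380, 4), seed = 1, ...) {
  synthetic_ligand_spec(
    classes = c("hydrophobic", "hbond_protein_donor", "hbond_protein_acceptor",
                "saltbridge_protein_positive"),
    characteristic_temperatures = temps, seed = seed, ...)
}

# quick low-resolution ramp for protocol-shape tests
quick_ramp <- function(...) build_ramp(300, 450, 10, durations = 2)
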