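# Shared fixture builders: tiny STAR files and toy atomic structures,
# all generated in code at test time.

write_min_star <- function(path, ids, rot, tilt, psi,
                           extra = NULL, drop_col = NULL) {
  df <- data.frame(rlnImageName = ids,
                   rlnMicrographName = rep("mic_0001.mrc", length(ids)),
                   rlnAngleRot = sprintf("%.6f", rot),
                   rlnAngleTilt = sprintf("%.6f", tilt),
                   rlnAnglePsi = sprintf("%.6f", psi),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra, stringsAsFactors = FALSE)
  if (!is.null(drop_col)) df[[drop_col]] <- NULL
  lines <- c("data_particles", "", "loop_",
             sprintf("_%s #%d", names(df), seq_along(df)),
             apply(as.matrix(df), 1, paste, collapse = " "))
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z, elem) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, resn, chain, resno, x, y, z, 1, 0, elem)
}

# Toy anchor/site geometry used across the tether tests: anchor on the
# static body, two sites at known cylinder radii about the z pivot axis.
toy_atoms <- function() {
  data.frame(serial = 1:3,
             name = c("CA", "SG", "OG"),
             resn = c("ALA", "CYS", "SER"),
             chain = "A",
             resno = c(2112L, 161L, 581L),
             x = c(10, 40, -35), y = c(0, 0, 20), z = c(5, 15, -5),
             elem = c("C", "S", "O"),
             stringsAsFactors = FALSE)
}

write_toy_pdb <- function(path, atoms = toy_atoms()) {
  lines <- vapply(seq_len(nrow(atoms)), function(i)
    with(atoms[i, ], pdb_atom_line(serial, name, resn, chain, resno,
                                   x, y, z, elem)), character(1))
  writeLines(c(lines, "END"), path)
  path
}

write_toy_cif <- function(path, atoms = toy_atoms()) {
  hdr <- paste0("_atom_site.",
                c("group_PDB", "id", "type_symbol", "label_atom_id",
                  "label_alt_id", "label_comp_id", "label_asym_id",
                  "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                  "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                  "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                  "auth_comp_id", "auth_asym_id", "auth_atom_id",
                  "pdbx_PDB_model_num"))
  rows <- vapply(seq_len(nrow(atoms)), function(i)
    with(atoms[i, ], sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
      serial, elem, name, resn, chain, resno, x, y, z, resno, resn, chain,
      name)), character(1))
  writeLines(c("data_toy", "#", "loop_", hdr, rows, "#"), path)
  path
}

# Independent dense-matrix builders used as oracles (never the package's
# own .Rz/.Ry/.Rx).
oracle_rz <- function(deg) {
  t <- deg * pi / 180
  rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0), c(0, 0, 1))
}
oracle_ry <- function(deg) {
  t <- deg * pi / 180
  rbind(c(cos(t), 0, sin(t)), c(0, 1, 0), c(-sin(t), 0, cos(t)))
}
oracle_rx <- function(deg) {
  t <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(t), -sin(t)), c(0, sin(t), cos(t)))
}

frob <- function(m) sqrt(sum(m^2))

# Wrapped per-axis distance used by brute-force oracles in tests.
oracle_wrap_dist <- function(p, q) {
  dw <- function(a, b) {
    d <- (a - b + 180) %% 360 - 180
    if (d <= -180) d <- d + 360
    d
  }
  sqrt(dw(p[1], q[1])^2 + (p[2] - q[2])^2 + dw(p[3], q[3])^2)
}
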