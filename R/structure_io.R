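#' @importFrom stats dist rnorm runif setNames
#' @importFrom utils combn head read.delim read.table write.table
NULL

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Parse a PDB file into target structures
#'
#' Reads ATOM records (plus selenomethionine HETATM records, remapped to
#' methionine) of the first model and produces one matchable target per
#' selected chain, or a single merged target.  Hetero residues, waters and
#' residues lacking a C-alpha record are excluded; alternate locations are
#' resolved by keeping the highest-occupancy conformer (ties broken by
#' altloc identifier order).  Residue identity is author numbering (chain,
#' sequence number, insertion code) throughout.
#'
#' @param pdb_text character: the PDB file content (single string or vector
#'   of lines).
#' @param chain_selection `"all-separate"` (default, one target per chain),
#'   `"merged"` (a single multi-chain target), or a character vector of
#'   chain identifiers (one target each).
#' @param id base identifier for the produced targets (e.g. the PDB code);
#'   chain identifiers are appended as `<id>_<chain>`.
#' @return a list of `target_structure` objects.  Each holds the residue
#'   table (author identifiers and labels), C-alpha coordinates, side-chain
#'   centroids, surface depths (`NA` until [compute_depth()] is run), the
#'   atom table used for depth/centroid computation, and residue label
#'   counts.
#' @export
parse_structure <- function(pdb_text, chain_selection = "all-separate",
                            id = "target") {
  lines <- split_pdb_lines(pdb_text)
  atoms <- parse_pdb_atoms(lines)
  chains <- unique(atoms$chain)
  merged <- identical(chain_selection, "merged")
  if (identical(chain_selection, "all-separate")) {
    wanted <- chains
  } else if (merged) {
    wanted <- chains
  } else {
    wanted <- as.character(chain_selection)
    missing <- setdiff(wanted, chains)
    if (length(missing))
      stop("chain(s) not found: ", paste(missing, collapse = ", "),
           "; available chains: ", paste(chains, collapse = ", "))
  }
  if (merged) {
    tid <- paste0(id, "_", paste(wanted, collapse = ""))
    list(build_target(atoms[atoms$chain %in% wanted, , drop = FALSE], tid))
  } else {
    lapply(wanted, function(ch)
      build_target(atoms[atoms$chain == ch, , drop = FALSE],
                   paste0(id, "_", ch)))
  }
}

split_pdb_lines <- function(pdb_text) {
  if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1L]]
  pdb_text
}

# Fixed-column PDB ATOM/HETATM parsing (first model only).  bio3d is used
# for heavier lifting elsewhere (read_pdb_file); this path works on in-memory
# text and gives us line-precise error reporting.
parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- substr(lines, 1L, 6L)
  is_atom <- trimws(rec) %in% c("ATOM", "HETATM")
  if (!any(is_atom)) {
    bad <- if (length(lines)) paste0("first line: '", lines[1L], "'") else "empty input"
    stop("no ATOM records found in PDB input (", bad, ")")
  }
  idx <- which(is_atom)
  ln <- lines[idx]
  short <- nchar(ln) < 54L
  if (any(short))
    stop("malformed ATOM record at line ", idx[short][1L], ": '",
         lines[idx[short][1L]], "'")
  x <- suppressWarnings(as.numeric(substr(ln, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(ln, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(ln, 47L, 54L)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stop("unparseable coordinates at line ", idx[bad[1L]], ": '", ln[bad[1L]], "'")
  occ <- suppressWarnings(as.numeric(substr(ln, 55L, 60L)))
  occ[!is.finite(occ)] <- 1
  elem <- trimws(substr(ln, 77L, 78L))
  name <- trimws(substr(ln, 13L, 16L))
  elem[elem == ""] <- substr(gsub("[0-9]", "", name[elem == ""]), 1L, 1L)
  data.frame(
    record = trimws(rec[is_atom]),
    name = name,
    altloc = substr(ln, 17L, 17L),
    resid = trimws(substr(ln, 18L, 20L)),
    chain = substr(ln, 22L, 22L),
    resno = as.integer(substr(ln, 23L, 26L)),
    ins = trimws(substr(ln, 27L, 27L)),
    x = x, y = y, z = z,
    occ = occ,
    element = elem,
    stringsAsFactors = FALSE)
}

build_target <- function(atoms, target_id) {
  # standard amino acids via bio3d's 3->1 mapping; MSE -> M; others dropped
  atoms <- atoms[atoms$record == "ATOM" | atoms$resid == "MSE", , drop = FALSE]
  atoms$resid[atoms$resid == "MSE"] <- "MET"
  lab3 <- atoms$resid
  lab1 <- suppressWarnings(bio3d::aa321(lab3))
  keep <- !is.na(lab1) & lab1 %in% AA1 & atoms$element != "H" & atoms$element != "D"
  atoms <- atoms[keep, , drop = FALSE]
  lab1 <- lab1[keep]
  if (!nrow(atoms))
    return(new_target_structure(target_id,
                                residues = empty_residue_frame(),
                                ca = matrix(numeric(), 0L, 3L),
                                centroid = matrix(numeric(), 0L, 3L),
                                centroid_flag = logical(),
                                atoms = atoms))
  file_order <- seq_len(nrow(atoms))
  rid <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  # altloc resolution per (residue, atom name): highest occupancy, ties by
  # altloc identifier order ("" sorts first)
  akey <- paste(rid, atoms$name, sep = "\r")
  ord <- order(akey, -atoms$occ, atoms$altloc)
  keep_alt <- ord[!duplicated(akey[ord])]
  keep_alt <- sort(keep_alt)  # restore file order
  atoms <- atoms[keep_alt, , drop = FALSE]
  lab1 <- lab1[keep_alt]
  rid <- rid[keep_alt]

  ures <- unique(rid)  # residues in order of first appearance
  res_index <- match(rid, ures)
  has_ca <- vapply(seq_along(ures), function(i)
    any(atoms$name[res_index == i] == "CA"), logical(1L))
  keep_res <- which(has_ca)
  ures <- ures[keep_res]
  keep_atom <- res_index %in% keep_res
  atoms <- atoms[keep_atom, , drop = FALSE]
  lab1 <- lab1[keep_atom]
  res_index <- match(rid[keep_atom], ures)

  n <- length(ures)
  parts <- strsplit(ures, "\r", fixed = TRUE)
  residues <- data.frame(
    chain_id = vapply(parts, `[`, "", 1L),
    seq_number = as.integer(vapply(parts, `[`, "", 2L)),
    insertion_code = vapply(parts, function(p)
      if (length(p) >= 3L) p[3L] else "", ""),
    label = lab1[match(seq_len(n), res_index)],
    stringsAsFactors = FALSE)
  ca <- matrix(NA_real_, n, 3L)
  ca_rows <- which(atoms$name == "CA")
  ca[res_index[ca_rows], ] <- as.matrix(atoms[ca_rows, c("x", "y", "z")])

  cen <- matrix(NA_real_, n, 3L)
  flag <- logical(n)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  side <- !(atoms$name %in% BACKBONE_ATOMS)
  for (i in seq_len(n)) {
    rows <- which(res_index == i & side)
    if (length(rows)) {
      cen[i, ] <- colMeans(xyz[rows, , drop = FALSE])
    } else {
      cen[i, ] <- ca[i, ]
      flag[i] <- residues$label[i] != "G"  # glycine: CA is the convention
    }
  }
  atoms_out <- data.frame(res_index = res_index, name = atoms$name,
                          element = atoms$element,
                          x = atoms$x, y = atoms$y, z = atoms$z,
                          stringsAsFactors = FALSE)
  new_target_structure(target_id, residues, ca, cen, flag, atoms_out)
}

empty_residue_frame <- function() {
  data.frame(chain_id = character(), seq_number = integer(),
             insertion_code = character(), label = character(),
             stringsAsFactors = FALSE)
}

new_target_structure <- function(target_id, residues, ca, centroid,
                                 centroid_flag, atoms = NULL,
                                 depth = rep(NA_real_, nrow(residues))) {
  ridkey <- paste(residues$chain_id, residues$seq_number,
                  residues$insertion_code)
  if (anyDuplicated(ridkey))
    stop("duplicate residue identifiers in target '", target_id, "': ",
         paste(unique(ridkey[duplicated(ridkey)]), collapse = ", "))
  structure(
    list(target_id = target_id,
         residues = residues,
         ca = ca,
         centroid = centroid,
         centroid_flag = centroid_flag,
         depth = depth,
         atoms = atoms,
         label_counts = count_labels(residues$label)),
    class = "target_structure")
}

count_labels <- function(labels) {
  if (!length(labels)) return(setNames(integer(), character()))
  tab <- table(labels)
  setNames(as.integer(tab), names(tab))
}

#' Residue label frequencies of a target
#'
#' Exact multiset counts of one-letter residue labels; these counts are
#' stored in the label table and drive the missed-match bookkeeping of the
#' significance model.
#'
#' @param target a `target_structure`.
#' @return named integer vector, one entry per occurring label.
#' @export
residue_frequencies <- function(target) {
  stopifnot(inherits(target, "target_structure"))
  count_labels(target$residues$label)
}

#' Compute per-residue surface depth
#'
#' Approximates each residue's distance to the molecular surface.  An atom
#' counts as *exposed* when it has fewer than `neighbor_threshold` heavy-atom
#' neighbors belonging to other residues within
#' `atom_radius + 2 * probe_radius`; a residue's depth is the minimum over
#' its atoms of the distance to the nearest exposed atom (zero when the
#' residue itself has an exposed atom).  This is a probe-ball occlusion
#' proxy for a solvent-excluded-surface computation; externally computed
#' depths can be supplied instead via [read_depth_sidecar()].
#'
#' @param target a `target_structure` with its atom table present.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param atom_radius heavy-atom radius in Angstrom (default 1.8).
#' @param neighbor_threshold exposure cutoff: an atom with fewer than this
#'   many external neighbors inside the probe shell is exposed (default 6).
#' @return the target with its `depth` vector filled in.
#' @export
compute_depth <- function(target, probe_radius = 1.4, atom_radius = 1.8,
                          neighbor_threshold = 6L) {
  stopifnot(inherits(target, "target_structure"))
  atoms <- target$atoms
  n_res <- nrow(target$residues)
  if (is.null(atoms) || nrow(atoms) < 4L) {
    if (n_res > 0L)
      warning("target '", target$target_id,
              "' has fewer than 4 atoms; all depths set to 0")
    target$depth <- rep(0, n_res)
    return(target)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  cutoff <- atom_radius + 2 * probe_radius
  D <- as.matrix(dist(xyz))
  ext <- outer(atoms$res_index, atoms$res_index, `!=`)
  ncount <- rowSums(D <= cutoff & ext)
  exposed <- ncount < neighbor_threshold
  if (!any(exposed)) {
    # pathological (fully occluded cluster): treat the least-occluded atoms
    # as the surface so depths stay finite
    exposed <- ncount == min(ncount)
  }
  d_to_surface <- apply(D[, exposed, drop = FALSE], 1L, min)
  d_to_surface[exposed] <- 0
  depth <- rep(0, n_res)
  for (i in seq_len(n_res)) {
    rows <- which(atoms$res_index == i)
    depth[i] <- if (length(rows)) min(d_to_surface[rows]) else 0
  }
  target$depth <- depth
  target
}

#' Side-chain centroid of one residue
#'
#' Mean of the non-backbone, non-hydrogen atom coordinates.  Glycine returns
#' the C-alpha position by convention; a non-glycine residue with no
#' side-chain atoms (truncated side chain) also falls back to C-alpha and is
#' flagged.
#'
#' @param target a `target_structure`.
#' @param index residue index within the target.
#' @return length-3 coordinate vector with attribute `fallback` (logical).
#' @export
sidechain_centroid <- function(target, index) {
  stopifnot(inherits(target, "target_structure"))
  v <- target$centroid[index, ]
  attr(v, "fallback") <- target$centroid_flag[index]
  v
}

#' Read per-residue depths from a sidecar file
#'
#' One line per residue: `chain seq_number insertion_code depth` (whitespace
#' separated; use `-` for an empty insertion code).  Residues present in the
#' target but absent from the file keep their current depth.
#'
#' @param target a `target_structure`.
#' @param path path to the sidecar file.
#' @return the target with depths overridden where supplied.
#' @export
read_depth_sidecar <- function(target, path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chain", "seq", "ins", "depth"))
  tab$ins[tab$ins == "-"] <- ""
  key <- paste(target$residues$chain_id, target$residues$seq_number,
               target$residues$insertion_code)
  fkey <- paste(tab$chain, tab$seq, tab$ins)
  hit <- match(key, fkey)
  ok <- !is.na(hit)
  if (is.null(target$depth)) target$depth <- rep(NA_real_, length(key))
  target$depth[ok] <- as.numeric(tab$depth[hit[ok]])
  target
}

#' Write a target back out as minimal PDB ATOM records
#'
#' Emits one ATOM record per stored atom (or, when the atom table has been
#' dropped, one C-alpha record per residue), preserving author numbering and
#' insertion codes at standard PDB coordinate precision (3 decimals).
#'
#' @param target a `target_structure`.
#' @return character vector of PDB lines (including a terminal `END`).
#' @export
write_minimal_pdb <- function(target) {
  res <- target$residues
  aa3 <- bio3d::aa123(res$label)
  fmt <- function(serial, name, resid, chain, resno, ins, x, y, z, element) {
    pad_name <- ifelse(nchar(name) < 4L, paste0(" ", name), name)
    sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, pad_name, resid, chain, resno, ifelse(ins == "", " ", ins),
            x, y, z, 1, 0, element)
  }
  lines <- character()
  serial <- 1L
  if (!is.null(target$atoms) && nrow(target$atoms)) {
    a <- target$atoms
    for (r in seq_len(nrow(res))) {
      rows <- which(a$res_index == r)
      for (j in rows) {
        lines <- c(lines, fmt(serial, a$name[j], aa3[r], res$chain_id[r],
                              res$seq_number[r], res$insertion_code[r],
                              a$x[j], a$y[j], a$z[j], a$element[j]))
        serial <- serial + 1L
      }
    }
  } else {
    for (r in seq_len(nrow(res))) {
      lines <- c(lines, fmt(serial, "CA", aa3[r], res$chain_id[r],
                            res$seq_number[r], res$insertion_code[r],
                            target$ca[r, 1], target$ca[r, 2], target$ca[r, 3],
                            "C"))
      serial <- serial + 1L
    }
  }
  c(lines, "END")
}

#' Read a PDB file from disk into target structures
#'
#' Thin wrapper around [parse_structure()]; the base identifier defaults to
#' the file name without extension.
#'
#' @param path path to a PDB file.
#' @inheritParams parse_structure
#' @return a list of `target_structure` objects.
#' @export
read_pdb_file <- function(path, chain_selection = "all-separate",
                          id = NULL) {
  if (is.null(id))
    id <- toupper(tools::file_path_sans_ext(basename(path)))
  parse_structure(readLines(path, warn = FALSE), chain_selection, id = id)
}

residue_id_string <- function(residues, i) {
  paste0(residues$chain_id[i], residues$seq_number[i], residues$insertion_code[i])
}

#' @export
print.target_structure <- function(x, ...) {
  cat("Target structure '", x$target_id, "': ", nrow(x$residues),
      " residues, ", length(unique(x$residues$chain_id)), " chain(s)\n",
      sep = "")
  if (all(is.na(x$depth))) cat("depths: not computed\n")
  else cat("depths: [", round(min(x$depth), 2), ", ",
           round(max(x$depth), 2), "] A\n", sep = "")
  invisible(x)
}

#' @export
summary.target_structure <- function(object, ...) {
  print(object)
  cat("label counts:\n")
  print(object$label_counts)
  invisible(object)
}
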