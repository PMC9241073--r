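# Internal topology table for the 20 standard amino-acid residues,
# AMBER-style atom naming. Each entry lists the sidechain bonds; backbone
# atoms/bonds are added by the template builder. Histidine is the neutral
# N-epsilon tautomer.
SIDECHAIN_BONDS <- list(
  ALA = "CB-HB1 CB-HB2 CB-HB3",
  ARG = paste("CB-HB2 CB-HB3 CB-CG CG-HG2 CG-HG3 CG-CD CD-HD2 CD-HD3",
              "CD-NE NE-HE NE-CZ CZ-NH1 NH1-HH11 NH1-HH12 CZ-NH2",
              "NH2-HH21 NH2-HH22"),
  ASN = "CB-HB2 CB-HB3 CB-CG CG-OD1 CG-ND2 ND2-HD21 ND2-HD22",
  ASP = "CB-HB2 CB-HB3 CB-CG CG-OD1 CG-OD2",
  CYS = "CB-HB2 CB-HB3 CB-SG SG-HG",
  GLN = paste("CB-HB2 CB-HB3 CB-CG CG-HG2 CG-HG3 CG-CD CD-OE1 CD-NE2",
              "NE2-HE21 NE2-HE22"),
  GLU = "CB-HB2 CB-HB3 CB-CG CG-HG2 CG-HG3 CG-CD CD-OE1 CD-OE2",
  GLY = "",
  HIS = paste("CB-HB2 CB-HB3 CB-CG CG-ND1 ND1-CE1 CE1-HE1 CE1-NE2",
              "NE2-HE2 NE2-CD2 CD2-HD2 CD2-CG"),
  ILE = paste("CB-HB CB-CG2 CG2-HG21 CG2-HG22 CG2-HG23 CB-CG1 CG1-HG12",
              "CG1-HG13 CG1-CD1 CD1-HD11 CD1-HD12 CD1-HD13"),
  LEU = paste("CB-HB2 CB-HB3 CB-CG CG-HG CG-CD1 CD1-HD11 CD1-HD12",
              "CD1-HD13 CG-CD2 CD2-HD21 CD2-HD22 CD2-HD23"),
  LYS = paste("CB-HB2 CB-HB3 CB-CG CG-HG2 CG-HG3 CG-CD CD-HD2 CD-HD3",
              "CD-CE CE-HE2 CE-HE3 CE-NZ NZ-HZ1 NZ-HZ2 NZ-HZ3"),
  MET = "CB-HB2 CB-HB3 CB-CG CG-HG2 CG-HG3 CG-SD SD-CE CE-HE1 CE-HE2 CE-HE3",
  PHE = paste("CB-HB2 CB-HB3 CB-CG CG-CD1 CD1-HD1 CD1-CE1 CE1-HE1 CE1-CZ",
              "CZ-HZ CZ-CE2 CE2-HE2 CE2-CD2 CD2-HD2 CD2-CG"),
  PRO = "N-CD CD-HD2 CD-HD3 CD-CG CG-HG2 CG-HG3 CG-CB CB-HB2 CB-HB3",
  SER = "CB-HB2 CB-HB3 CB-OG OG-HG",
  THR = "CB-HB CB-OG1 OG1-HG1 CB-CG2 CG2-HG21 CG2-HG22 CG2-HG23",
  TRP = paste("CB-HB2 CB-HB3 CB-CG CG-CD1 CD1-HD1 CD1-NE1 NE1-HE1",
              "NE1-CE2 CE2-CZ2 CZ2-HZ2 CZ2-CH2 CH2-HH2 CH2-CZ3 CZ3-HZ3",
              "CZ3-CE3 CE3-HE3 CE3-CD2 CD2-CE2 CD2-CG"),
  TYR = paste("CB-HB2 CB-HB3 CB-CG CG-CD1 CD1-HD1 CD1-CE1 CE1-HE1 CE1-CZ",
              "CZ-OH OH-HH CZ-CE2 CE2-HE2 CE2-CD2 CD2-HD2 CD2-CG"),
  VAL = paste("CB-HB CB-CG1 CG1-HG11 CG1-HG12 CG1-HG13 CB-CG2 CG2-HG21",
              "CG2-HG22 CG2-HG23")
)

atom_element <- function(name) {
  ifelse(substr(name, 1, 1) == "S", "S", substr(name, 1, 1))
}

#' Load a standard residue topology template
#'
#' Templates carry conventional AMBER-style atom names and the covalent
#' bond graph. Backbone atoms N, H, CA, HA, C, O are present for every
#' residue (glycine carries HA2/HA3 instead of HA; proline lacks the amide
#' H and closes its ring onto N).
#'
#' @param code Standard 3-letter residue code (case-insensitive).
#' @return A list of class `residue_template`: `code`, `atoms` (tibble of
#'   `name`, `element`), `bonds` (tibble of `from`, `to`).
#' @export
load_template <- function(code) {
  code <- toupper(code)
  if (!code %in% names(SIDECHAIN_BONDS)) {
    rlang::abort(sprintf("Unknown residue code '%s'.", code))
  }
  bb_bonds <- if (code == "GLY") {
    c("N-H", "N-CA", "CA-HA2", "CA-HA3", "CA-C", "C-O")
  } else if (code == "PRO") {
    c("N-CA", "CA-HA", "CA-C", "C-O", "CA-CB")
  } else {
    c("N-H", "N-CA", "CA-HA", "CA-C", "C-O", "CA-CB")
  }
  sc <- trimws(SIDECHAIN_BONDS[[code]])
  all_bonds <- bb_bonds
  if (nzchar(sc)) {
    all_bonds <- c(all_bonds, strsplit(sc, "\\s+")[[1]])
  }
  pairs <- do.call(rbind, strsplit(all_bonds, "-", fixed = TRUE))
  bonds <- tibble::tibble(from = pairs[, 1], to = pairs[, 2])
  bonds <- dplyr::distinct(bonds)
  atom_names <- unique(c(bonds$from, bonds$to))
  # stable, conventional order: backbone first, then sidechain by appearance
  bb_order <- intersect(c("N", "H", "CA", "HA", "HA2", "HA3", "C", "O"),
                        atom_names)
  atom_names <- c(bb_order, setdiff(atom_names, bb_order))
  structure(
    list(
      code = code,
      atoms = tibble::tibble(name = atom_names,
                             element = atom_element(atom_names)),
      bonds = bonds
    ),
    class = "residue_template"
  )
}

as_template <- function(x) {
  if (inherits(x, "residue_template")) x else load_template(x)
}

has_bond <- function(tpl, a, b) {
  any((tpl$bonds$from == a & tpl$bonds$to == b) |
      (tpl$bonds$from == b & tpl$bonds$to == a))
}

neighbors_of <- function(tpl, a) {
  unique(c(tpl$bonds$to[tpl$bonds$from == a],
           tpl$bonds$from[tpl$bonds$to == a]))
}

backbone_names <- function(tpl) {
  intersect(tpl$atoms$name, c("N", "H", "CA", "HA", "HA2", "HA3", "C", "O"))
}

# Pair the backbone atoms of two templates: identical names pair directly;
# alpha hydrogens (HA vs HA2/HA3) are zipped in sorted name order with any
# surplus left unique (so GLY -> X pairs HA2 with HA and leaves HA3 unique).
backbone_pairs <- function(src, tgt) {
  sb <- backbone_names(src)
  tb <- backbone_names(tgt)
  heavy_h <- intersect(intersect(sb, tb), c("N", "CA", "C", "O", "H"))
  ha_s <- sort(intersect(sb, c("HA", "HA2", "HA3")))
  ha_t <- sort(intersect(tb, c("HA", "HA2", "HA3")))
  k <- min(length(ha_s), length(ha_t))
  tibble::tibble(
    source = c(heavy_h, ha_s[seq_len(k)]),
    target = c(heavy_h, ha_t[seq_len(k)])
  )
}

new_atom_mapping <- function(pairs, src, tgt, scheme) {
  structure(
    list(
      pairs = pairs,
      unique_source = setdiff(src$atoms$name, pairs$source),
      unique_target = setdiff(tgt$atoms$name, pairs$target),
      scheme = scheme,
      source_code = src$code,
      target_code = tgt$code
    ),
    class = "atom_mapping"
  )
}

#' Default (all-sidechain-softcore) atom mapping
#'
#' The conservative scheme for a single-residue alchemical transformation:
#' backbone atoms are paired and transformed linearly, while every
#' sidechain atom on either side is unique and handled with softcore
#' potentials. Glycine's surplus alpha hydrogen counts as unique.
#'
#' @param src,tgt Residue codes or `residue_template`s (source and target
#'   end states).
#' @return An `atom_mapping` with `scheme = "default"`.
#' @export
default_mapping <- function(src, tgt) {
  src <- as_template(src)
  tgt <- as_template(tgt)
  new_atom_mapping(backbone_pairs(src, tgt), src, tgt, "default")
}

#' Maximum-common-substructure atom mapping
#'
#' Grows the common core outward from the paired backbone along the bond
#' graphs of both residues, pairing atoms of identical element while
#' preserving bond structure (each accepted pair must be bond-consistent
#' with every previously accepted pair on both sides). Ties are broken
#' deterministically: heavy atoms before hydrogens, then lexicographic
#' atom name; when a paired heavy atom carries more hydrogens on one side
#' (e.g. serine CB vs threonine CB), hydrogens are paired in lexicographic
#' order and the surplus stays unique. Minimizing the unique-atom sets
#' this way preserves interactions of the retained chemistry: for
#' THR->SER only the threonine terminal methyl group and the corresponding
#' serine beta-hydrogen remain unique (the -CbHOH group is common), and
#' for PHE<->TYR only the tyrosine hydroxyl and the matching ring hydrogen
#' of phenylalanine are softcore.
#'
#' @inheritParams default_mapping
#' @return An `atom_mapping` with `scheme = "mcs"`.
#' @export
mcs_mapping <- function(src, tgt) {
  src <- as_template(src)
  tgt <- as_template(tgt)
  pairs <- backbone_pairs(src, tgt)
  matched_s <- pairs$source
  matched_t <- pairs$target
  queue <- seq_len(nrow(pairs))

  bond_consistent <- function(a, b) {
    for (i in seq_along(matched_s)) {
      if (has_bond(src, a, matched_s[i]) != has_bond(tgt, b, matched_t[i])) {
        return(FALSE)
      }
    }
    TRUE
  }

  while (length(queue) > 0L) {
    i <- queue[1]
    queue <- queue[-1]
    a <- matched_s[i]
    b <- matched_t[i]
    cand_a <- setdiff(neighbors_of(src, a), matched_s)
    cand_b <- setdiff(neighbors_of(tgt, b), matched_t)
    if (length(cand_a) == 0L || length(cand_b) == 0L) next
    elems <- union(atom_element(cand_a), atom_element(cand_b))
    elems <- c(sort(setdiff(elems, "H")), intersect(elems, "H"))
    for (el in elems) {
      sa <- sort(cand_a[atom_element(cand_a) == el])
      sb <- sort(cand_b[atom_element(cand_b) == el])
      for (k in seq_len(min(length(sa), length(sb)))) {
        if (sa[k] %in% matched_s || sb[k] %in% matched_t) next
        if (!bond_consistent(sa[k], sb[k])) next
        matched_s <- c(matched_s, sa[k])
        matched_t <- c(matched_t, sb[k])
        queue <- c(queue, length(matched_s))
      }
    }
  }
  new_atom_mapping(
    tibble::tibble(source = matched_s, target = matched_t),
    src, tgt, "mcs"
  )
}

#' Validate an atom mapping against its two templates
#'
#' Checks that (i) paired and unique atoms form exact partitions of each
#' template's atom set, (ii) every pair matches elements, and (iii) the
#' paired subgraphs are isomorphic: for every two pairs, a bond on the
#' source side exists iff the corresponding bond exists on the target
#' side. Violations are reported, not thrown, so hand-written mappings can
#' be audited.
#'
#' @param mapping An `atom_mapping` (from [default_mapping()],
#'   [mcs_mapping()], or built manually).
#' @param src,tgt The two residue codes or templates.
#' @return A tibble of violations (columns `type`, `detail`); zero rows
#'   means the mapping is valid.
#' @export
validate_mapping <- function(mapping, src = mapping$source_code,
                             tgt = mapping$target_code) {
  src <- as_template(src)
  tgt <- as_template(tgt)
  v <- list()
  add <- function(type, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(type = type, detail = detail)
  }
  ps <- mapping$pairs$source
  pt <- mapping$pairs$target
  cover_s <- c(ps, mapping$unique_source)
  cover_t <- c(pt, mapping$unique_target)
  if (anyDuplicated(cover_s)) {
    add("partition", sprintf("source atom(s) listed twice: %s",
                             paste(cover_s[duplicated(cover_s)], collapse = ",")))
  }
  if (anyDuplicated(cover_t)) {
    add("partition", sprintf("target atom(s) listed twice: %s",
                             paste(cover_t[duplicated(cover_t)], collapse = ",")))
  }
  miss_s <- setdiff(src$atoms$name, cover_s)
  if (length(miss_s)) {
    add("partition", sprintf("source atom(s) unassigned: %s",
                             paste(miss_s, collapse = ",")))
  }
  miss_t <- setdiff(tgt$atoms$name, cover_t)
  if (length(miss_t)) {
    add("partition", sprintf("target atom(s) unassigned: %s",
                             paste(miss_t, collapse = ",")))
  }
  extra_s <- setdiff(cover_s, src$atoms$name)
  if (length(extra_s)) {
    add("partition", sprintf("unknown source atom(s): %s",
                             paste(extra_s, collapse = ",")))
  }
  extra_t <- setdiff(cover_t, tgt$atoms$name)
  if (length(extra_t)) {
    add("partition", sprintf("unknown target atom(s): %s",
                             paste(extra_t, collapse = ",")))
  }
  for (i in seq_along(ps)) {
    if (ps[i] %in% src$atoms$name && pt[i] %in% tgt$atoms$name &&
        atom_element(ps[i]) != atom_element(pt[i])) {
      add("element", sprintf("%s (%s) paired with %s (%s)",
                             ps[i], atom_element(ps[i]),
                             pt[i], atom_element(pt[i])))
    }
  }
  if (length(ps) >= 2L) {
    for (i in seq_len(length(ps) - 1L)) {
      for (j in (i + 1L):length(ps)) {
        bs <- has_bond(src, ps[i], ps[j])
        bt <- has_bond(tgt, pt[i], pt[j])
        if (bs != bt) {
          add("isomorphism", sprintf(
            "bond %s-%s %s in source but %s-%s %s in target",
            ps[i], ps[j], if (bs) "present" else "absent",
            pt[i], pt[j], if (bt) "present" else "absent"
          ))
        }
      }
    }
  }
  if (length(v) == 0L) {
    tibble::tibble(type = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' @export
print.atom_mapping <- function(x, ...) {
  cat(sprintf("<atom_mapping> %s -> %s (%s scheme)\n",
              x$source_code, x$target_code, x$scheme))
  cat(sprintf("  %d paired atoms (common core)\n", nrow(x$pairs)))
  cat(sprintf("  unique source: %s\n",
              paste(x$unique_source, collapse = " ")))
  cat(sprintf("  unique target: %s\n",
              paste(x$unique_target, collapse = " ")))
  invisible(x)
}

#' Tidy an atom mapping into one row per atom
#'
#' @param x An `atom_mapping`.
#' @param ... Unused.
#' @return A tibble with columns `role` (`pair`, `unique_source`,
#'   `unique_target`), `source`, `target`.
#' @method tidy atom_mapping
#' @export
tidy.atom_mapping <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$pairs, role = "pair", .before = 1),
    tibble::tibble(role = "unique_source", source = x$unique_source,
                   target = NA_character_),
    tibble::tibble(role = "unique_target", source = NA_character_,
                   target = x$unique_target)
  )
}
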