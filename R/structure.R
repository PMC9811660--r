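#' Describe a spin-label attachment site on a structure
#'
#' Crystal structures of candidate complexes carry no nitroxide label; the
#' label position is approximated by a pseudo-atom built from the backbone of
#' the cysteine-mutated residue. Two placement rules are provided:
#' `"cbeta"` uses the C-beta position itself (a conservative lower bound on
#' probe-nucleus distances), and `"cbeta_extended"` (default) extends the
#' Ca-to-Cb vector by `extension_length` Å to approximate the nitroxide
#' midpoint of the label side chain.
#'
#' @param chain_id Chain identifier in the structure carrying the label site.
#' @param residue_number Author residue number of the labeled (cysteine) site.
#' @param placement_rule `"cbeta_extended"` or `"cbeta"`.
#' @param extension_length Extension along the Ca->Cb unit vector, Å
#'   (used by `"cbeta_extended"`).
#' @return An object of class `probe_site`.
#' @examples
#' probe_site("B", 27)
#' @export
probe_site <- function(chain_id, residue_number,
                       placement_rule = c("cbeta_extended", "cbeta"),
                       extension_length = 7.0) {
  placement_rule <- match.arg(placement_rule)
  if (extension_length < 0) stop("extension_length must be >= 0")
  structure(
    list(chain_id = as.character(chain_id),
         residue_number = as.integer(residue_number),
         placement_rule = placement_rule,
         extension_length = extension_length),
    class = "probe_site"
  )
}

#' Define a candidate binding mode
#'
#' A binding mode couples a candidate complex structure with a spin-label
#' site and the chain carrying the isotope-labeled (observed) protein, and
#' optionally a mapping from construct residue numbering to the numbering
#' used in the structure.
#'
#' @param name Mode label, e.g. `"primary"` or `"tripartite"`.
#' @param structure_source Path to the PDB or mmCIF file of the candidate
#'   complex.
#' @param probe A [probe_site()].
#' @param observed_chain Chain id of the observed protein in the structure.
#' @param chain_map Optional named integer vector mapping structure residue
#'   numbers (values) to construct residue numbers (names); must be
#'   injective. `NULL` means numbering is shared.
#' @return An object of class `binding_mode`.
#' @export
binding_mode <- function(name, structure_source, probe, observed_chain,
                         chain_map = NULL) {
  if (!inherits(probe, "probe_site")) stop("probe must be a probe_site object")
  if (!is.null(chain_map)) {
    if (is.null(names(chain_map)) || anyDuplicated(names(chain_map)) ||
        anyDuplicated(chain_map)) {
      stop("chain_map must be a named vector with unique names and values ",
           "(injective residue-number mapping)")
    }
  }
  structure(
    list(name = as.character(name),
         structure_source = structure_source,
         probe = probe,
         observed_chain = as.character(observed_chain),
         chain_map = chain_map),
    class = "binding_mode"
  )
}

#' Load a complex structure from PDB or mmCIF
#'
#' Thin wrapper over `bio3d` readers that keeps author residue numbering and
#' coordinates exactly as stored. The format is chosen from the file
#' extension (`.cif` -> mmCIF, otherwise PDB).
#'
#' @param source Path to a PDB or mmCIF file.
#' @return A `bio3d` `pdb` object.
#' @export
load_structure <- function(source) {
  if (!is.character(source) || length(source) != 1L) {
    stop("source must be a single file path")
  }
  if (!file.exists(source)) stop("structure file not found: ", source)
  reader <- if (grepl("\\.cif$", source, ignore.case = TRUE)) {
    bio3d::read.cif
  } else {
    bio3d::read.pdb
  }
  pdb <- tryCatch(
    suppressWarnings(reader(source)),
    error = function(e) {
      stop("failed to parse structure file '", source, "': ",
           conditionMessage(e))
    }
  )
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L) {
    stop("structure file '", source, "' contains no atom records")
  }
  pdb
}

atom_xyz <- function(pdb, chain, resno, elety) {
  a <- pdb$atom
  hit <- a$chain == chain & a$resno == resno & a$elety == elety
  if (!any(hit)) return(NULL)
  as.numeric(a[which(hit)[1], c("x", "y", "z")])
}

#' Place the spin-label pseudo-atom
#'
#' Applies the probe-site placement rule: `"cbeta"` returns the C-beta
#' coordinate (C-alpha for glycine, with a warning); `"cbeta_extended"`
#' returns Cb + extension_length * unit(Ca -> Cb).
#'
#' @param structure A structure from [load_structure()].
#' @param site A [probe_site()].
#' @return Numeric xyz coordinates of the probe, Å.
#' @export
place_probe <- function(structure, site) {
  if (!inherits(site, "probe_site")) stop("site must be a probe_site object")
  ca <- atom_xyz(structure, site$chain_id, site$residue_number, "CA")
  if (is.null(ca)) {
    stop("probe residue ", site$residue_number, " in chain ", site$chain_id,
         " has no CA atom (or is absent from the structure)")
  }
  cb <- atom_xyz(structure, site$chain_id, site$residue_number, "CB")
  if (is.null(cb)) {
    warning("probe residue ", site$residue_number, " in chain ",
            site$chain_id, " has no CB (glycine?); using CA position")
    return(ca)
  }
  if (site$placement_rule == "cbeta") return(cb)
  v <- cb - ca
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate CA/CB geometry at probe residue ",
                    site$residue_number)
  cb + site$extension_length * v / nv
}

#' Probe-nucleus distance table for a binding mode
#'
#' Places the spin-label pseudo-atom and measures its Euclidean distance to
#' the requested nucleus of every residue of the observed chain. Crystal
#' structures usually lack amide hydrogens; if `atom_role = "amide_H"` and no
#' H atoms are present, distances are measured to the backbone N instead and
#' the table is flagged (`attr(, "used_N_for_H")`), adding roughly 1 Å of
#' systematic uncertainty. For `"methyl_C"` the nearest methyl carbon of each
#' Ile/Leu/Val residue is used.
#'
#' @param structure A structure from [load_structure()].
#' @param mode A [binding_mode()].
#' @param atom_role `"amide_N"`, `"amide_H"` or `"methyl_C"`.
#' @return A data frame (class `distance_table`) with columns `residue`,
#'   `atom_role`, `distance_A`, `mode`, `placement_rule`. Residues of the
#'   observed chain lacking the requested atom are listed in
#'   `attr(, "missing_residues")`, not silently dropped.
#' @export
distance_table <- function(structure, mode,
                           atom_role = c("amide_N", "amide_H", "methyl_C")) {
  atom_role <- match.arg(atom_role)
  if (!inherits(mode, "binding_mode")) stop("mode must be a binding_mode")
  probe <- place_probe(structure, mode$probe)

  a <- structure$atom
  obs <- a[a$chain == mode$observed_chain & a$type == "ATOM", , drop = FALSE]
  if (nrow(obs) == 0L) {
    stop("observed chain '", mode$observed_chain,
         "' is empty or absent from the structure")
  }
  residues <- sort(unique(obs$resno))

  used_N_for_H <- FALSE
  target_rows <- switch(atom_role,
    amide_N = obs[obs$elety == "N", , drop = FALSE],
    amide_H = {
      h <- obs[obs$elety %in% c("H", "HN"), , drop = FALSE]
      if (nrow(h) == 0L) {
        used_N_for_H <- TRUE
        obs[obs$elety == "N", , drop = FALSE]
      } else h
    },
    methyl_C = {
      methyl <- list(ILE = c("CG2", "CD1"), LEU = c("CD1", "CD2"),
                     VAL = c("CG1", "CG2"))
      keep <- mapply(function(res, ele) {
        !is.null(methyl[[res]]) && ele %in% methyl[[res]]
      }, obs$resid, obs$elety)
      obs[keep, , drop = FALSE]
    })
  if (atom_role == "methyl_C") residues <- sort(unique(target_rows$resno))

  d <- vapply(residues, function(rn) {
    rows <- target_rows[target_rows$resno == rn, , drop = FALSE]
    if (nrow(rows) == 0L) return(NA_real_)
    xyz <- as.matrix(rows[, c("x", "y", "z")])
    min(sqrt(rowSums(sweep(xyz, 2, probe)^2)))
  }, numeric(1))

  if (!is.null(mode$chain_map)) {
    mapped <- match(residues, mode$chain_map)
    keep <- !is.na(mapped)
    residues <- as.integer(names(mode$chain_map)[mapped[keep]])
    d <- d[keep]
  }

  out <- data.frame(
    residue = residues[!is.na(d)],
    atom_role = if (used_N_for_H) "amide_N" else atom_role,
    distance_A = d[!is.na(d)],
    mode = mode$name,
    placement_rule = mode$probe$placement_rule,
    stringsAsFactors = FALSE
  )
  class(out) <- c("distance_table", "data.frame")
  attr(out, "missing_residues") <- residues[is.na(d)]
  attr(out, "used_N_for_H") <- used_N_for_H
  out
}

#' Residues expected to show strong PREs for a binding mode
#'
#' Returns the residues of a distance table whose predicted intensity ratio
#' at bound fraction `p` falls below `threshold` — the detection footprint a
#' genuinely populated mode must light up.
#'
#' @param table A [distance_table()].
#' @param params A [spin_params()] object.
#' @param threshold Intensity-ratio threshold defining "strong" (default 0.4).
#' @param p Assumed bound fraction (default 1, full occupancy).
#' @return Sorted integer vector of residue numbers.
#' @examples
#' # distances 10 and 18 A fall inside the full-occupancy 0.4 footprint
#' # (~18.5 A); 25 A does not.
#' @export
strong_pre_footprint <- function(table, params = spin_params(),
                                 threshold = 0.4, p = 1) {
  if (!is.data.frame(table) || !all(c("residue", "distance_A") %in%
                                    names(table))) {
    stop("table must be a distance_table data frame")
  }
  if (p == 0) return(integer(0))
  pre <- predicted_pre(table$distance_A, p, params)
  sort(unique(table$residue[pre < threshold]))
}

#' Write a distance table as TSV
#'
#' @param table A [distance_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
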