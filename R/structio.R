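#' Structure container for protein-DNA complexes
#'
#' A \code{StructureModel} holds the atoms of one model of a deposited or
#' synthetic complex as a data frame, plus per-chain roles and optional
#' crystallographic metadata. Residue numbering is always taken verbatim
#' from the source; the package never renumbers.
#'
#' @param atoms data frame with columns \code{atom_name}, \code{element},
#'   \code{residue_name}, \code{residue_number}, \code{chain_id},
#'   \code{x}, \code{y}, \code{z}, \code{is_hetero}.
#' @param chain_roles named character vector mapping chain id to one of
#'   \code{"integrase"}, \code{"dna_top"}, \code{"dna_bottom"},
#'   \code{"other"}. Inferred from residue chemistry when \code{NULL}.
#' @param cell optional unit cell \code{c(a, b, c, alpha, beta, gamma)}
#'   (Angstrom / degrees).
#' @param space_group optional space-group symbol (e.g. \code{"I23"}).
#' @return An object of class \code{StructureModel}.
#' @export
structure_model <- function(atoms, chain_roles = NULL, cell = NULL,
                            space_group = NULL) {
  need <- c("atom_name", "element", "residue_name", "residue_number",
            "chain_id", "x", "y", "z", "is_hetero")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("structure_model: atoms lacks columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("structure_model: empty atom table")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("structure_model: non-finite coordinates")
  atoms <- as.data.frame(atoms)[, need]
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$residue_number <- as.integer(atoms$residue_number)
  if (is.null(chain_roles)) chain_roles <- infer_chain_roles(atoms)
  bad <- setdiff(names(chain_roles), unique(atoms$chain_id))
  if (length(bad)) stop("structure_model: chain_roles name absent chains: ",
                        paste(bad, collapse = ", "))
  structure(list(atoms = atoms, chain_roles = chain_roles, cell = cell,
                 space_group = space_group),
            class = "StructureModel")
}

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
NT_RES <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U")

#' Infer chain roles from residue chemistry
#'
#' A chain whose polymer residues are amino acids is \code{integrase};
#' nucleotide chains become \code{dna_top} / \code{dna_bottom} in order of
#' first appearance (the assignment is a convention and can be overridden
#' in \code{\link{structure_model}}); anything else (ions, solvent) is
#' \code{other}.
#'
#' @param atoms atom data frame as in \code{\link{structure_model}}.
#' @return named character vector of roles.
#' @export
infer_chain_roles <- function(atoms) {
  chains <- unique(atoms$chain_id)
  dna_seen <- 0L
  roles <- character(length(chains)); names(roles) <- chains
  for (ch in chains) {
    res <- unique(atoms$residue_name[atoms$chain_id == ch & !atoms$is_hetero])
    if (length(res) == 0)
      res <- unique(atoms$residue_name[atoms$chain_id == ch])
    if (mean(res %in% AA3) > 0.5) roles[ch] <- "integrase"
    else if (mean(res %in% NT_RES) > 0.5) {
      dna_seen <- dna_seen + 1L
      roles[ch] <- if (dna_seen %% 2L == 1L) "dna_top" else "dna_bottom"
    } else roles[ch] <- "other"
  }
  roles
}

#' Coordinates of a structure as a matrix
#' @param model a \code{StructureModel}.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' @export
apply_transform.StructureModel <- function(t, x) {
  xyz <- apply_transform(t, coords(x))
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain_id)), "chains")
  if (!is.null(x$space_group)) cat(",", x$space_group)
  cat("\n")
  rl <- x$chain_roles
  cat("  chains:", paste(sprintf("%s[%s]", names(rl), rl), collapse = " "),
      "\n")
  invisible(x)
}

merge_structures <- function(...) {
  ms <- list(...)
  atoms <- do.call(rbind, lapply(ms, function(m) m$atoms))
  roles <- do.call(c, unname(lapply(ms, function(m) m$chain_roles)))
  if (anyDuplicated(names(roles)))
    stop("merge_structures: duplicated chain ids: ",
         paste(unique(names(roles)[duplicated(names(roles))]), collapse = ", "))
  structure_model(atoms, roles, cell = ms[[1]]$cell,
                  space_group = ms[[1]]$space_group)
}

rename_chains <- function(model, map) {
  old <- names(map)
  stopifnot(all(old %in% unique(model$atoms$chain_id)))
  model$atoms$chain_id <- ifelse(model$atoms$chain_id %in% old,
                                 unname(map[model$atoms$chain_id]),
                                 model$atoms$chain_id)
  nm <- names(model$chain_roles)
  names(model$chain_roles) <- ifelse(nm %in% old, unname(map[nm]), nm)
  model
}

# ---------------------------------------------------------------------------
# Coordinate file input / output

#' Read a macromolecular coordinate file
#'
#' PDB files are parsed through bio3d; mmCIF files through a minimal
#' \code{atom_site} loop reader. Only the first model of multi-model files
#' is kept; for alternate locations the highest-occupancy conformer wins
#' (ties: first encountered).
#'
#' @param path file path.
#' @param dialect \code{"pdb"} or \code{"mmcif"}.
#' @param chain_roles optional role override (see
#'   \code{\link{structure_model}}).
#' @return A \code{StructureModel}.
#' @export
read_structure <- function(path, dialect = c("pdb", "mmcif"),
                           chain_roles = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  if (dialect == "pdb") read_structure_pdb(path, chain_roles)
  else read_structure_mmcif(path, chain_roles)
}

read_structure_pdb <- function(path, chain_roles) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("read_structure: cannot parse PDB file '", path,
                         "': ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0)
    stop("read_structure: no ATOM/HETATM records in ", path)
  # alternate locations: keep highest occupancy, tie -> first encountered
  alt <- a$alt; alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(a$chain, a$resno, a$insert, a$elety)
    occ <- a$o; occ[is.na(occ)] <- 1
    keep <- !logical(nrow(a))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[which.max(occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    a <- a[keep, , drop = FALSE]
  }
  ele <- a$elesy
  ele[is.na(ele) | ele == ""] <- substr(trimws(a$elety[is.na(ele) | ele == ""]), 1, 1)
  chain <- a$chain; chain[is.na(chain) | chain == ""] <- " "
  atoms <- data.frame(atom_name = trimws(a$elety), element = trimws(ele),
                      residue_name = trimws(a$resid),
                      residue_number = a$resno, chain_id = chain,
                      x = a$x, y = a$y, z = a$z,
                      is_hetero = a$type == "HETATM",
                      stringsAsFactors = FALSE)
  cryst <- tryCatch(pdb$cryst1, error = function(e) NULL)
  cell <- sg <- NULL
  if (!is.null(cryst) && length(cryst$abc) == 3) {
    cell <- c(cryst$abc, cryst$angles)
    sg <- gsub(" ", "", cryst$sGroup %||% "")
    if (identical(sg, "")) sg <- NULL
  }
  structure_model(atoms, chain_roles, cell = cell, space_group = sg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_structure_mmcif <- function(path, chain_roles) {
  lines <- readLines(path, warn = FALSE)
  i <- grep("^\\s*loop_\\s*$", lines)
  blk <- NULL
  for (s in i) {
    j <- s + 1
    fields <- character()
    while (j <= length(lines) && grepl("^_", trimws(lines[j]))) {
      fields <- c(fields, trimws(lines[j])); j <- j + 1
    }
    if (any(grepl("^_atom_site\\.", fields))) { blk <- list(start = j, fields = fields); break }
  }
  if (is.null(blk))
    stop("read_structure: no _atom_site loop in mmCIF file ", path)
  fields <- sub("^_atom_site\\.", "", blk$fields)
  rows <- list(); j <- blk$start
  while (j <= length(lines)) {
    ln <- trimws(lines[j])
    if (ln == "" || grepl("^(#|loop_|_|data_)", ln)) break
    rows[[length(rows) + 1L]] <- scan(text = ln, what = character(),
                                      quiet = TRUE)
    j <- j + 1
  }
  if (length(rows) == 0)
    stop("read_structure: empty _atom_site loop in ", path)
  bad <- which(lengths(rows) != length(fields))
  if (length(bad))
    stop("read_structure: malformed _atom_site record at data row ", bad[1],
         " of ", path)
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- fields
  get <- function(...) {
    for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
    NULL
  }
  model_num <- get("pdbx_PDB_model_num")
  if (!is.null(model_num)) tab <- tab[model_num == model_num[1], , drop = FALSE]
  get2 <- function(...) {
    for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
    NULL
  }
  grp <- get2("group_PDB") %||% rep("ATOM", nrow(tab))
  atoms <- data.frame(
    atom_name = gsub('"', "", get2("auth_atom_id", "label_atom_id")),
    element = get2("type_symbol") %||% "",
    residue_name = get2("auth_comp_id", "label_comp_id"),
    residue_number = as.integer(get2("auth_seq_id", "label_seq_id")),
    chain_id = get2("auth_asym_id", "label_asym_id"),
    x = as.numeric(get2("Cartn_x")), y = as.numeric(get2("Cartn_y")),
    z = as.numeric(get2("Cartn_z")),
    is_hetero = grp == "HETATM", stringsAsFactors = FALSE)
  # alternate locations
  altloc <- get2("label_alt_id")
  if (!is.null(altloc)) {
    altloc[altloc %in% c(".", "?")] <- ""
    occ <- suppressWarnings(as.numeric(get2("occupancy") %||% 1))
    occ[is.na(occ)] <- 1
    if (any(altloc != "")) {
      key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
      keep <- !logical(nrow(atoms))
      for (k in unique(key[duplicated(key)])) {
        idx <- which(key == k)
        keep[setdiff(idx, idx[which.max(occ[idx])])] <- FALSE
      }
      atoms <- atoms[keep, , drop = FALSE]
    }
  }
  structure_model(atoms, chain_roles)
}

#' Write a structure to a coordinate file
#'
#' PDB output goes through bio3d and round-trips atom names, residue
#' numbers and coordinates at 3-decimal precision; mmCIF output writes a
#' standard \code{atom_site} loop. PDB limits are enforced explicitly:
#' more than 99,999 atoms or multi-character chain ids are an error for
#' the \code{pdb} dialect rather than silent truncation.
#'
#' @param model a \code{StructureModel}.
#' @param path output file path.
#' @param dialect \code{"pdb"} or \code{"mmcif"}.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(model, path, dialect = c("pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms
  if (nrow(a) == 0) stop("write_structure: empty model")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("write_structure: no such directory: ", dir)
  if (dialect == "pdb") {
    if (nrow(a) > 99999L)
      stop("write_structure: ", nrow(a),
           " atoms exceed the PDB serial limit (99999); use dialect 'mmcif'")
    if (any(nchar(a$chain_id) > 1L))
      stop("write_structure: chain ids longer than 1 character are not ",
           "representable in PDB format: ",
           paste(unique(a$chain_id[nchar(a$chain_id) > 1]), collapse = ", "),
           " (use dialect 'mmcif')")
    xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
    suppressWarnings(bio3d::write.pdb(
      file = path, xyz = xyz,
      type = ifelse(a$is_hetero, "HETATM", "ATOM"),
      resno = a$residue_number, resid = a$residue_name,
      chain = a$chain_id, elety = a$atom_name, elesy = a$element,
      eleno = seq_len(nrow(a)), o = rep(1, nrow(a)), b = rep(0, nrow(a))))
  } else {
    hdr <- c("data_attarch", "#", "loop_",
             paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                     "label_atom_id", "label_comp_id",
                                     "label_asym_id", "auth_asym_id",
                                     "auth_seq_id", "Cartn_x", "Cartn_y",
                                     "Cartn_z", "occupancy",
                                     "pdbx_PDB_model_num")))
    an <- ifelse(grepl("'", a$atom_name), paste0('"', a$atom_name, '"'),
                 a$atom_name)
    recs <- sprintf("%-6s %d %s %s %s %s %s %d %.3f %.3f %.3f 1.00 1",
                    ifelse(a$is_hetero, "HETATM", "ATOM"),
                    seq_len(nrow(a)), a$element, an, a$residue_name,
                    a$chain_id, a$chain_id, a$residue_number,
                    a$x, a$y, a$z)
    ok <- tryCatch({ writeLines(c(hdr, recs, "#"), path); TRUE },
                   error = function(e) stop("write_structure: cannot write ",
                                            path, ": ", conditionMessage(e)))
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Domain annotation

#' Integrase domain annotation scheme
#'
#' The default scheme encodes the LI (Listeria phage) integrase C-terminal
#' domain: the crystallized construct spans residues 133-452; the
#' coiled-coil (CC) motif is the 342-416 insertion between the zinc-ribbon
#' helices, the zinc-ribbon domain (ZD) spans 265-452 with the CC carved
#' out, the recombinase domain plus the alphaE stub and the 8-residue
#' RD-ZD linker fill 133-264. The ZD anchor is the Calpha of Ala338 at the
#' end of alphaJ and the CC tip is Tyr374 at the centre of the turn
#' between the CC helices. Zinc is coordinated by Cys274, Cys277, Cys302
#' and Cys314.
#'
#' Alternative schemes can be loaded from a YAML file with
#' \code{\link{read_domain_scheme}}.
#'
#' @return A named list of domain descriptors, each with \code{range}
#'   (inclusive) and optional \code{metadata}.
#' @export
li_domain_scheme <- function() {
  list(
    alphaE = list(range = c(133L, 140L)),
    RD = list(range = c(141L, 256L)),
    RD_ZD_linker = list(range = c(257L, 264L)),
    ZD = list(range = c(265L, 452L), carve_out = "CC",
              metadata = list(zinc_cysteines = c(274L, 277L, 302L, 314L))),
    CC = list(range = c(342L, 416L)),
    ZD_anchor = list(range = c(338L, 338L),
                     metadata = list(residue = "ALA", atom = "CA")),
    CC_tip = list(range = c(374L, 374L),
                  metadata = list(residue = "TYR", atom = "CA"))
  )
}

#' Read a domain annotation scheme from YAML
#'
#' @param path YAML file: top-level keys are domain names, each with a
#'   \code{range: [start, end]} entry and optional \code{metadata}.
#' @return scheme list as in \code{\link{li_domain_scheme}}.
#' @export
read_domain_scheme <- function(path) {
  sc <- yaml::read_yaml(path)
  lapply(sc, function(d) {
    d$range <- as.integer(d$range)
    d
  })
}

#' Annotate integrase domains on a chain
#'
#' Applies an annotation scheme (residue ranges in the chain's own
#' numbering) to one integrase chain, tolerating disordered gaps inside a
#' range (missing residues are reported in a warning); a missing anchor or
#' tip residue is an error because downstream distance measurements need
#' it.
#'
#' @param model a \code{StructureModel}.
#' @param chain_id chain to annotate.
#' @param scheme annotation scheme (default \code{\link{li_domain_scheme}}).
#' @param warn_missing warn about residues in a range absent from the
#'   chain (default TRUE).
#' @return list of \code{DomainAnnotation} entries: \code{name},
#'   \code{range}, \code{residues_present}, \code{residues_missing},
#'   \code{metadata}.
#' @export
annotate_domains <- function(model, chain_id, scheme = li_domain_scheme(),
                             warn_missing = TRUE) {
  stopifnot(inherits(model, "StructureModel"))
  if (!chain_id %in% names(model$chain_roles))
    stop("annotate_domains: unknown chain ", chain_id)
  if (model$chain_roles[[chain_id]] != "integrase")
    stop("annotate_domains: chain ", chain_id, " is not an integrase chain")
  present <- sort(unique(
    model$atoms$residue_number[model$atoms$chain_id == chain_id]))
  out <- lapply(names(scheme), function(nm) {
    d <- scheme[[nm]]
    r <- d$range
    if (length(r) != 2 || r[2] < r[1])
      stop("annotate_domains: empty or invalid range for domain ", nm)
    span <- seq.int(r[1], r[2])
    if (!is.null(d$carve_out) && d$carve_out %in% names(scheme)) {
      co <- scheme[[d$carve_out]]$range
      span <- setdiff(span, seq.int(co[1], co[2]))
    }
    here <- intersect(span, present)
    missing <- setdiff(span, present)
    if (nm %in% c("ZD_anchor", "CC_tip") && length(here) == 0)
      stop("annotate_domains: ", nm, " residue ", r[1],
           " absent from chain ", chain_id)
    if (warn_missing && length(missing) && length(here) &&
        !nm %in% c("ZD_anchor", "CC_tip"))
      warning("annotate_domains: ", nm, ": ", length(missing),
              " residues of ", r[1], "-", r[2], " absent from chain ",
              chain_id, " (e.g. ",
              paste(utils::head(missing, 5), collapse = ", "), ")",
              call. = FALSE)
    structure(list(name = nm, range = r, residues_present = here,
                   residues_missing = missing,
                   metadata = d$metadata %||% list()),
              class = "DomainAnnotation")
  })
  names(out) <- names(scheme)
  out
}

# ---------------------------------------------------------------------------
# Crystallographic bookkeeping

#' Asymmetric-unit contents of a crystal
#'
#' @param proteins list of \code{list(residues =, copies =)} entries (or
#'   \code{sequence =} instead of a residue count).
#' @param dnas list of \code{list(bp =, copies =)} entries (duplex base
#'   pairs).
#' @param zinc_ions number of zinc ions per asymmetric unit.
#' @return An object of class \code{CellContents}.
#' @export
cell_contents <- function(proteins = list(), dnas = list(), zinc_ions = 0L) {
  for (p in proteins)
    if (is.null(p$residues) && is.null(p$sequence))
      stop("cell_contents: protein entry needs residues or sequence")
  counts <- c(vapply(proteins, function(p) p$copies %||% 1, numeric(1)),
              vapply(dnas, function(d) d$copies %||% 1, numeric(1)),
              zinc_ions)
  if (any(counts < 0)) stop("cell_contents: negative copy counts")
  structure(list(proteins = proteins, dnas = dnas,
                 zinc_ions = as.integer(zinc_ions)),
            class = "CellContents")
}

contents_mass <- function(contents, protein_da_per_residue = 110,
                          dna_da_per_bp = 660) {
  pm <- sum(vapply(contents$proteins, function(p) {
    n <- if (!is.null(p$sequence)) nchar(gsub("\\s", "", p$sequence))
         else p$residues
    n * protein_da_per_residue * (p$copies %||% 1)
  }, numeric(1)), 0)
  dm <- sum(vapply(contents$dnas, function(d)
    d$bp * dna_da_per_bp * (d$copies %||% 1), numeric(1)), 0)
  zm <- contents$zinc_ions * 65.4
  c(protein = pm, dna = dm, zinc = zm)
}

SPACE_GROUP_Z <- c(
  "P1" = 1, "P-1" = 2, "P2" = 2, "P21" = 2, "C2" = 4, "P222" = 4,
  "P212121" = 4, "P21212" = 4, "C2221" = 8, "I222" = 8, "P4" = 4,
  "P41" = 4, "P43" = 4, "P41212" = 8, "P43212" = 8, "P3" = 3, "P31" = 3,
  "P32" = 3, "P3121" = 6, "P3221" = 6, "P6" = 6, "P61" = 6, "P6122" = 12,
  "R3" = 9, "R32" = 18, "P23" = 12, "P213" = 12, "I23" = 24, "I213" = 24,
  "F23" = 48, "P432" = 24, "I432" = 48, "F432" = 96, "F4132" = 96,
  "P4132" = 24, "P4332" = 24, "I4132" = 48)

cell_volume <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  a * b * c * sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
                   2 * cos(al) * cos(be) * cos(ga))
}

#' Crystal solvent fraction via the Matthews relation
#'
#' Computes the Matthews coefficient Vm = V_cell / (Z * M_asu) and returns
#' the solvent fraction 1 - k/Vm. The default k = 1.23 A^3/Da is the
#' standard protein convention, applied here to the total macromolecular
#' mass (protein at 110 Da/residue unless a sequence is given, DNA at
#' 660 Da/bp); pass per-component partial specific volumes via
#' \code{vbar_protein} / \code{vbar_dna} (cm^3/g) to weight the components
#' separately instead.
#'
#' @param cell unit cell \code{c(a, b, c, alpha, beta, gamma)}.
#' @param space_group space-group symbol, used to look up the number of
#'   asymmetric units per cell.
#' @param contents a \code{\link{cell_contents}} object.
#' @param k packing coefficient (A^3/Da) for the 1 - k/Vm convention.
#' @param vbar_protein,vbar_dna optional partial specific volumes; if both
#'   given, the macromolecular volume fraction is computed per component.
#' @param protein_da_per_residue,dna_da_per_bp mass defaults.
#' @return solvent fraction in [0, 1].
#' @export
solvent_fraction <- function(cell, space_group, contents, k = 1.23,
                             vbar_protein = NULL, vbar_dna = NULL,
                             protein_da_per_residue = 110,
                             dna_da_per_bp = 660) {
  sg <- gsub("[ ()]", "", space_group)
  if (!sg %in% names(SPACE_GROUP_Z))
    stop("solvent_fraction: unknown space group symbol '", space_group, "'")
  V <- cell_volume(cell)
  if (!is.finite(V) || V <= 0) stop("solvent_fraction: zero or invalid cell volume")
  Z <- SPACE_GROUP_Z[[sg]]
  m <- contents_mass(contents, protein_da_per_residue, dna_da_per_bp)
  M <- sum(m)
  if (M == 0) return(1.0)
  if (!is.null(vbar_protein) && !is.null(vbar_dna)) {
    # volume per Da = vbar[cm^3/g] * 1e24 / N_A = vbar * 1.66054 A^3/Da
    vol <- (m[["protein"]] * vbar_protein + (m[["dna"]] + m[["zinc"]]) *
              vbar_dna) * 1.66054
    frac <- 1 - Z * vol / V
  } else {
    vm <- V / (Z * M)
    frac <- 1 - k / vm
  }
  min(1, max(0, frac))
}

#' Matthews coefficient
#' @inheritParams solvent_fraction
#' @return Vm in A^3/Da.
#' @export
matthews_vm <- function(cell, space_group, contents,
                        protein_da_per_residue = 110, dna_da_per_bp = 660) {
  sg <- gsub("[ ()]", "", space_group)
  if (!sg %in% names(SPACE_GROUP_Z))
    stop("matthews_vm: unknown space group symbol '", space_group, "'")
  M <- sum(contents_mass(contents, protein_da_per_residue, dna_da_per_bp))
  if (M == 0) stop("matthews_vm: empty contents")
  cell_volume(cell) / (SPACE_GROUP_Z[[sg]] * M)
}
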