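#' @keywords internal
bead_labels <- function(topology) {
  name <- rep("X", topology$n_beads)
  role <- rep("-", topology$n_beads)
  roles <- c("NC3", "PO4", "GL1", "GL2", "C4A", "C4B")
  lip <- topology$lipids
  if (nrow(lip) > 0) {
    for (r in roles) {
      name[lip[[r]]] <- r
      role[lip[[r]]] <- r
    }
  }
  res <- topology$residues
  if (nrow(res) > 0) {
    name[res$backbone] <- "BB"
    role[res$backbone] <- "BB"
    for (i in seq_len(nrow(res))) {
      sc <- res$sidechain[[i]]
      if (length(sc) > 0) {
        name[sc] <- paste0("SC", seq_along(sc))
        role[sc] <- "SC"
      }
    }
  }
  name[topology$waters] <- "W"
  role[topology$waters] <- "W"
  if (nrow(topology$ions) > 0) {
    name[topology$ions$bead] <- topology$ions$species
    role[topology$ions$bead] <- "ION"
  }
  list(name = name, role = role)
}

serialize_topology <- function(topology) {
  list(
    n_beads = topology$n_beads,
    lipids = topology$lipids,
    residues = if (nrow(topology$residues) > 0) {
      r <- topology$residues
      list(resid = r$resid, chain = r$chain, backbone = r$backbone,
           sidechain = r$sidechain, tm = r$tm)
    },
    waters = topology$waters,
    ions = topology$ions
  )
}

deserialize_topology <- function(hdr) {
  residues <- NULL
  if (!is.null(hdr$residues) && length(hdr$residues$resid) > 0) {
    residues <- tibble::tibble(
      resid = as.integer(hdr$residues$resid),
      chain = as.character(hdr$residues$chain),
      backbone = as.integer(hdr$residues$backbone),
      sidechain = lapply(hdr$residues$sidechain, as.integer),
      tm = as.character(hdr$residues$tm)
    )
  }
  ions <- NULL
  if (!is.null(hdr$ions) && length(hdr$ions) > 0 && length(hdr$ions$bead) > 0) {
    ions <- tibble::tibble(bead = as.integer(hdr$ions$bead),
                           species = as.character(hdr$ions$species))
  }
  lipids <- tibble::as_tibble(hdr$lipids)
  if (nrow(lipids) == 0) {
    lipids <- tibble::tibble(lipid = integer(), NC3 = integer(),
                             PO4 = integer(), GL1 = integer(),
                             GL2 = integer(), C4A = integer(),
                             C4B = integer(), leaflet = character())
  }
  cg_topology(lipids = lipids, residues = residues,
              waters = as.integer(unlist(hdr$waters)),
              ions = ions, n_beads = as.integer(hdr$n_beads))
}

#' Write a trajectory in the package's plain-text fixture format
#'
#' The format is a single text file: a magic line, a JSON header carrying the
#' full topology, then per frame a `FRAME <i> <time> <bx> <by> <bz>` line
#' followed by one `name role x y z` line per bead. Coordinates are written
#' with 17 significant digits so a write/read round trip is exact to double
#' precision. Intended for small fixtures, not production trajectories.
#'
#' @param traj A [cg_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cg_trajectory <- function(traj, path) {
  lab <- bead_labels(traj$topology)
  hdr <- jsonlite::toJSON(serialize_topology(traj$topology),
                          auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#MEMSCRAMBLE-TRAJ 1", as.character(hdr)), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("FRAME %d %.17g %.17g %.17g %.17g", f, traj$times[f],
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
    m <- traj$coords[, , f]
    writeLines(sprintf("%s %s %.17g %.17g %.17g", lab$name, lab$role,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read a trajectory from the package's fixture format
#'
#' @param path File written by [write_cg_trajectory()].
#' @return A [cg_trajectory()].
#' @export
read_cg_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "#MEMSCRAMBLE-TRAJ")) {
    stop("format error: not a memscramble fixture file", call. = FALSE)
  }
  topo <- deserialize_topology(jsonlite::fromJSON(lines[2],
                                                  simplifyVector = TRUE))
  body <- lines[-(1:2)]
  frame_at <- which(startsWith(body, "FRAME "))
  nf <- length(frame_at)
  if (nf == 0) stop("format error: no frames", call. = FALSE)
  per <- if (nf > 1) diff(frame_at)[1] - 1L else length(body) - 1L
  if (per != topo$n_beads) {
    stop("format error: frame bead count (", per,
         ") does not match topology size (", topo$n_beads, ")", call. = FALSE)
  }
  hdr_fields <- do.call(rbind, strsplit(body[frame_at], " ", fixed = TRUE))
  times <- as.numeric(hdr_fields[, 3])
  box <- matrix(as.numeric(hdr_fields[, 4:6]), ncol = 3)
  bead_lines <- body[-frame_at]
  fields <- strsplit(bead_lines, " ", fixed = TRUE)
  if (any(lengths(fields) != 5L)) {
    stop("format error: malformed bead line", call. = FALSE)
  }
  fm <- matrix(unlist(fields), ncol = 5, byrow = TRUE)
  xyz <- matrix(as.numeric(fm[, 3:5]), ncol = 3)
  coords <- array(NA_real_, dim = c(topo$n_beads, 3L, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- xyz[((f - 1L) * topo$n_beads + 1L):(f * topo$n_beads), ]
  }
  cg_trajectory(coords, times, box, topo)
}

#' Read a trajectory from standard structure files
#'
#' Reads either the package's own fixture format (single file) or a
#' multi-model PDB snapshot series via the bio3d package, combined with a
#' role map that resolves lipid bead roles and protein residue metadata.
#' XTC/GRO are not supported (no reader available in R); convert such
#' trajectories to multi-model PDB or the fixture format first.
#'
#' @param topology_file Fixture file or PDB file.
#' @param frames_file Optional multi-model PDB with the frames; defaults to
#'   `topology_file`.
#' @param role_map For PDB input, a list with elements `lipid_resnames`
#'   (residue names treated as lipids, default `"DOPC"`), `bead_roles` (named
#'   character vector mapping atom names to the roles NC3, PO4, GL1, GL2, C4A,
#'   C4B), `water_resnames` (default `"W"`), `ion_names` (named vector atom
#'   name -> species), and `tm_ranges` (tibble `resid_first`, `resid_last`,
#'   `tm`).
#' @param times Frame times in ns for PDB input (default `1:n` ns).
#' @param box Box lengths for PDB input (default from CRYST1 if present, else
#'   an error).
#' @return A [cg_trajectory()].
#' @export
read_trajectory <- function(topology_file, frames_file = topology_file,
                            role_map = NULL, times = NULL, box = NULL) {
  if (!file.exists(topology_file)) {
    stop("file not found: ", topology_file, call. = FALSE)
  }
  first <- readLines(topology_file, n = 1L)
  if (startsWith(first, "#MEMSCRAMBLE-TRAJ")) {
    return(read_cg_trajectory(topology_file))
  }
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB trajectories requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(frames_file, multi = TRUE)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  nb <- ncol(xyz) / 3
  at <- pdb$atom
  rm <- role_map %||% list()
  lipid_resnames <- rm$lipid_resnames %||% "DOPC"
  bead_roles <- rm$bead_roles %||% stats::setNames(
    c("NC3", "PO4", "GL1", "GL2", "C4A", "C4B"),
    c("NC3", "PO4", "GL1", "GL2", "C4A", "C4B"))
  water_resnames <- rm$water_resnames %||% "W"
  ion_names <- rm$ion_names %||% c(NA. = "Na", CL = "Cl", CA = "Ca")

  is_lipid <- at$resid %in% lipid_resnames
  lip_ids <- unique(at$resno[is_lipid])
  roles <- c("NC3", "PO4", "GL1", "GL2", "C4A", "C4B")
  lipids <- NULL
  if (length(lip_ids) > 0) {
    rows <- lapply(lip_ids, function(id) {
      sel <- which(is_lipid & at$resno == id)
      idx <- stats::setNames(rep(NA_integer_, 6), roles)
      for (j in sel) {
        r <- bead_roles[[at$elety[j]]]
        if (!is.null(r) && !is.na(r)) idx[[r]] <- j
      }
      if (anyNA(idx)) {
        stop("topology error: lipid ", id, " is missing bead role(s): ",
             paste(roles[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      c(lipid = id, as.list(idx))
    })
    lipids <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    lipids$leaflet <- "unassigned"
  }
  is_water <- at$resid %in% water_resnames
  is_ion <- at$elety %in% names(ion_names)
  ions <- NULL
  if (any(is_ion)) {
    ions <- tibble::tibble(bead = which(is_ion),
                           species = unname(ion_names[at$elety[is_ion]]))
  }
  is_protein <- !is_lipid & !is_water & !is_ion
  residues <- NULL
  if (any(is_protein)) {
    pro <- which(is_protein)
    key <- paste(at$chain[pro], at$resno[pro])
    grp <- split(pro, factor(key, levels = unique(key)))
    residues <- dplyr::bind_rows(lapply(grp, function(sel) {
      bb <- sel[at$elety[sel] == "BB"]
      if (length(bb) == 0) bb <- sel[1]
      tibble::tibble(resid = at$resno[sel[1]],
                     chain = at$chain[sel[1]] %||% "A",
                     backbone = bb[1],
                     sidechain = list(setdiff(sel, bb[1])),
                     tm = NA_character_)
    }))
    if (!is.null(rm$tm_ranges)) {
      tr <- rm$tm_ranges
      for (i in seq_len(nrow(tr))) {
        hit <- residues$resid >= tr$resid_first[i] & residues$resid <= tr$resid_last[i]
        residues$tm[hit] <- tr$tm[i]
      }
    }
  }
  topo <- cg_topology(lipids = lipids %||% tibble::tibble(
    lipid = integer(), NC3 = integer(), PO4 = integer(), GL1 = integer(),
    GL2 = integer(), C4A = integer(), C4B = integer(), leaflet = character()),
    residues = residues, waters = which(is_water), ions = ions, n_beads = nb)

  coords <- array(NA_real_, dim = c(nb, 3L, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  if (is.null(times)) times <- seq_len(nf)
  if (is.null(box)) {
    if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3) {
      box <- pdb$cryst1$abc
    } else {
      stop("format error: no box information; supply `box`", call. = FALSE)
    }
  }
  cg_trajectory(coords, times, box, topo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
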