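#' Build a coarse-grained topology
#'
#' A topology maps global bead indices (1-based) to their molecular roles:
#' lipid role beads (NC3, PO4, GL1, GL2, C4A, C4B per lipid), protein residues
#' (backbone bead plus zero or more side-chain beads), water beads, and ions.
#' Residue numbers follow the experimental (author-provided) numbering so that
#' published transmembrane-segment ranges apply verbatim.
#'
#' @param lipids Tibble with columns `lipid` (id), `NC3`, `PO4`, `GL1`, `GL2`,
#'   `C4A`, `C4B` (bead indices) and `leaflet` (`"upper"`, `"lower"` or
#'   `"unassigned"` initial label).
#' @param residues Tibble with columns `resid` (residue number), `chain`
#'   (subunit id), `backbone` (bead index), `sidechain` (list-column of integer
#'   bead indices, possibly empty as for glycine) and `tm` (TM-segment label,
#'   e.g. `"TM4"`, or `NA`). May be `NULL` for protein-free systems.
#' @param waters Integer vector of water bead indices.
#' @param ions Tibble with columns `bead` and `species` (`"Na"`, `"Cl"` or
#'   `"Ca"`), or `NULL`.
#' @param n_beads Total number of beads in every frame.
#'
#' @return An object of class `cg_topology`.
#' @export
cg_topology <- function(lipids, residues = NULL, waters = integer(),
                        ions = NULL, n_beads) {
  lipids <- tibble::as_tibble(lipids)
  roles <- c("NC3", "PO4", "GL1", "GL2", "C4A", "C4B")
  missing_roles <- setdiff(c("lipid", roles), names(lipids))
  if (nrow(lipids) > 0 && length(missing_roles) > 0) {
    stop("topology error: lipid roles not resolved: ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  }
  if (!"leaflet" %in% names(lipids)) lipids$leaflet <- "unassigned"
  if (is.null(residues)) {
    residues <- tibble::tibble(resid = integer(), chain = character(),
                               backbone = integer(),
                               sidechain = list(), tm = character())
  }
  residues <- tibble::as_tibble(residues)
  if (nrow(residues) > 0 && !"sidechain" %in% names(residues)) {
    residues$sidechain <- replicate(nrow(residues), integer(), simplify = FALSE)
  }
  if (nrow(residues) > 0 && !"tm" %in% names(residues)) residues$tm <- NA_character_
  if (is.null(ions)) {
    ions <- tibble::tibble(bead = integer(), species = character())
  }
  ions <- tibble::as_tibble(ions)

  topo <- structure(
    list(lipids = lipids, residues = residues,
         waters = as.integer(waters), ions = ions,
         n_beads = as.integer(n_beads)),
    class = "cg_topology"
  )
  validate_cg_topology(topo)
}

validate_cg_topology <- function(topo) {
  roles <- c("NC3", "PO4", "GL1", "GL2", "C4A", "C4B")
  lip <- topo$lipids
  if (nrow(lip) > 0) {
    role_mat <- as.matrix(lip[, roles])
    if (anyNA(role_mat)) {
      stop("topology error: missing bead role for at least one lipid",
           call. = FALSE)
    }
    dup_within <- apply(role_mat, 1L, function(r) anyDuplicated(r) > 0)
    if (any(dup_within)) {
      stop("topology error: lipid role beads must be distinct (lipid ",
           lip$lipid[which(dup_within)[1]], ")", call. = FALSE)
    }
  }
  all_idx <- c(
    if (nrow(lip) > 0) as.vector(as.matrix(lip[, roles])),
    topo$residues$backbone,
    unlist(topo$residues$sidechain),
    topo$waters,
    topo$ions$bead
  )
  all_idx <- as.integer(all_idx)
  if (anyDuplicated(all_idx) > 0) {
    stop("topology error: bead indices must be globally unique", call. = FALSE)
  }
  if (length(all_idx) > 0 && (min(all_idx) < 1L || max(all_idx) > topo$n_beads)) {
    stop("topology error: bead index outside 1..n_beads", call. = FALSE)
  }
  topo
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("<cg_topology> ", x$n_beads, " beads: ",
      nrow(x$lipids), " lipids, ",
      nrow(x$residues), " residues, ",
      length(x$waters), " waters, ",
      nrow(x$ions), " ions\n", sep = "")
  invisible(x)
}

#' Bead indices of selected residues
#'
#' @param topology A [cg_topology()].
#' @param resid Residue numbers to select (`NULL` for all).
#' @param chain Chain id(s) to select (`NULL` for all).
#' @param tm TM-segment label(s) to select (`NULL` for all).
#' @param what `"all"` (backbone plus side chain), `"backbone"` or
#'   `"sidechain"`.
#' @return Integer vector of bead indices.
#' @export
residue_beads <- function(topology, resid = NULL, chain = NULL, tm = NULL,
                          what = c("all", "backbone", "sidechain")) {
  what <- match.arg(what)
  res <- topology$residues
  if (!is.null(resid)) res <- res[res$resid %in% resid, ]
  if (!is.null(chain)) res <- res[res$chain %in% chain, ]
  if (!is.null(tm)) res <- res[!is.na(res$tm) & res$tm %in% tm, ]
  if (nrow(res) == 0) {
    stop("selection error: no residues match the selection", call. = FALSE)
  }
  bb <- res$backbone
  sc <- unlist(res$sidechain)
  switch(what,
         all = as.integer(c(bb, sc)),
         backbone = as.integer(bb),
         sidechain = as.integer(sc))
}
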