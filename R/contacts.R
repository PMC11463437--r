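#' Residue-lipid contact series
#'
#' For every frame, measures the distance between the residue's outermost
#' side-chain bead (the side-chain bead farthest from its backbone bead in
#' that frame; the backbone bead itself for glycine-like residues without
#' side chains) and the lipid's choline (NC3) or phosphate (PO4) bead. A
#' contact is a distance strictly below the cutoff (7 A).
#'
#' @param traj A [cg_trajectory()].
#' @param resid Residue number.
#' @param lipid Lipid id.
#' @param bead `"NC3"` or `"PO4"`.
#' @param chain Chain id (default `"A"`).
#' @param cutoff Contact cutoff (A, strict `<`, default 7).
#' @return Tibble with columns `time`, `distance`, `contact` (logical).
#' @export
contact_frames <- function(traj, resid, lipid, bead = c("NC3", "PO4"),
                           chain = "A", cutoff = 7) {
  bead <- match.arg(bead)
  res <- traj$topology$residues
  row <- res[res$resid == resid & res$chain == chain, ]
  if (nrow(row) == 0) stop("selection error: residue not found", call. = FALSE)
  lip <- traj$topology$lipids
  lrow <- lip[lip$lipid == lipid, ]
  if (nrow(lrow) == 0) stop("selection error: lipid not found", call. = FALSE)
  lb <- lrow[[bead]]
  bb <- row$backbone[1]
  sc <- row$sidechain[[1]]
  nf <- n_frames(traj)
  lx <- traj$coords[lb, , ]                       # 3 x nf
  if (length(sc) == 0) {
    px <- traj$coords[bb, , ]
  } else if (length(sc) == 1) {
    px <- traj$coords[sc, , ]
  } else {
    scx <- traj$coords[sc, , , drop = FALSE]      # k x 3 x nf
    bbx <- traj$coords[bb, , ]                    # 3 x nf
    d2 <- (scx[, 1, ] - rep(bbx[1, ], each = length(sc)))^2 +
      (scx[, 2, ] - rep(bbx[2, ], each = length(sc)))^2 +
      (scx[, 3, ] - rep(bbx[3, ], each = length(sc)))^2
    d2 <- matrix(d2, nrow = length(sc))
    pick <- max.col(t(d2), ties.method = "first")
    px <- sapply(seq_len(nf), function(f) scx[pick[f], , f])
  }
  px <- matrix(px, nrow = 3)
  lx <- matrix(lx, nrow = 3)
  d <- sqrt(colSums((px - lx)^2))
  tibble::tibble(time = traj$times, distance = d, contact = d < cutoff)
}

#' Merge a contact series into dwell intervals
#'
#' Maximal runs of contact frames, merged across interruptions of up to
#' `gap_ns` (6 ns): any gap of at most `gap_ns / dt` consecutive
#' non-contact frames joins its flanking runs. Dwell time counts both
#' endpoints inclusively (and includes merged gap frames):
#' `dwell = (end_frame - start_frame + 1) * dt`.
#'
#' @param contacts Logical vector, or a tibble with a `contact` column (and
#'   `time`, as from [contact_frames()]).
#' @param gap_ns Gap tolerance (ns, default 6).
#' @param dt Frame spacing in ns (default 1; taken from `time` if present).
#' @return Tibble with columns `t_start`, `t_end`, `dwell_ns`,
#'   `n_contact_frames`.
#' @export
dwell_intervals <- function(contacts, gap_ns = 6, dt = 1) {
  if (is.data.frame(contacts)) {
    if ("time" %in% names(contacts) && nrow(contacts) > 1) {
      dt <- contacts$time[2] - contacts$time[1]
      t0 <- contacts$time[1]
    } else {
      t0 <- dt
    }
    x <- contacts$contact
  } else {
    x <- contacts
    t0 <- dt
  }
  empty <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                          dwell_ns = numeric(), n_contact_frames = integer())
  if (!any(x)) return(empty)
  gap_frames <- max(0L, as.integer(round(gap_ns / dt)))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by gaps of <= gap_frames false frames
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= gap_frames) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  n_true <- vapply(seq_len(nrow(merged)), function(i) {
    sum(x[merged$start[i]:merged$end[i]])
  }, integer(1))
  tibble::tibble(
    t_start = t0 + (merged$start - 1L) * dt,
    t_end = t0 + (merged$end - 1L) * dt,
    dwell_ns = (merged$end - merged$start + 1L) * dt,
    n_contact_frames = n_true
  )
}

#' Mean dwell of the top-50% longest dwell events
#'
#' Mean over the longer half of the dwell events (ceiling count for odd
#' event numbers); by construction at least the median dwell.
#'
#' @param dwells Numeric vector of dwell times (ns).
#' @return Numeric scalar (0 for no events).
#' @export
top_half_dwell <- function(dwells) {
  if (length(dwells) == 0) return(0)
  k <- ceiling(length(dwells) / 2)
  mean(sort(dwells, decreasing = TRUE)[seq_len(k)])
}

#' Per-residue contact summary
#'
#' For one residue number: builds contact timelines against each given lipid
#' for both headgroup bead choices (NC3 and PO4), keeps the bead with the
#' higher mean dwell time, and reports the contact frequency (fraction of
#' frames with at least one lipid contact, averaged over the chains carrying
#' the residue - the two monomers), the mean dwell of the top-50% longest
#' dwell events, and the share of contact frames attributable to scrambling
#' lipids.
#'
#' @param traj A [cg_trajectory()].
#' @param resid Residue number (summarized across all chains carrying it).
#' @param lipids Lipid ids to consider (default: all).
#' @param scramblers Lipid ids that scramble (default none).
#' @param cutoff Contact cutoff (A, default 7).
#' @param gap_ns Dwell gap tolerance (ns, default 6).
#' @return One-row tibble: `resid`, `bead`, `frequency`, `mean_dwell_top50`,
#'   `scrambler_share`, `n_events`, `no_contacts` flag.
#' @export
summarize_residue_contacts <- function(traj, resid, lipids = NULL,
                                       scramblers = integer(), cutoff = 7,
                                       gap_ns = 6) {
  res <- traj$topology$residues
  chains <- unique(res$chain[res$resid == resid])
  if (length(chains) == 0) {
    stop("selection error: residue not found", call. = FALSE)
  }
  if (is.null(lipids)) lipids <- traj$topology$lipids$lipid
  nf <- n_frames(traj)
  per_bead <- list()
  for (bead in c("NC3", "PO4")) {
    dwells <- numeric()
    freq_by_chain <- numeric(length(chains))
    scram_frames <- 0L
    all_frames <- 0L
    for (ci in seq_along(chains)) {
      any_contact <- rep(FALSE, nf)
      for (lp in lipids) {
        cf <- contact_frames(traj, resid, lp, bead = bead,
                             chain = chains[ci], cutoff = cutoff)
        if (any(cf$contact)) {
          iv <- dwell_intervals(cf, gap_ns = gap_ns)
          dwells <- c(dwells, iv$dwell_ns)
          any_contact <- any_contact | cf$contact
          nct <- sum(cf$contact)
          all_frames <- all_frames + nct
          if (lp %in% scramblers) scram_frames <- scram_frames + nct
        }
      }
      freq_by_chain[ci] <- mean(any_contact)
    }
    per_bead[[bead]] <- list(
      mean_dwell = if (length(dwells) > 0) mean(dwells) else 0,
      dwells = dwells, frequency = mean(freq_by_chain),
      scram_frames = scram_frames, all_frames = all_frames)
  }
  bead <- if (per_bead$NC3$mean_dwell >= per_bead$PO4$mean_dwell) {
    "NC3"
  } else {
    "PO4"
  }
  b <- per_bead[[bead]]
  tibble::tibble(
    resid = resid, bead = bead, frequency = b$frequency,
    mean_dwell_top50 = top_half_dwell(b$dwells),
    scrambler_share = if (b$all_frames > 0) {
      b$scram_frames / b$all_frames
    } else {
      0
    },
    n_events = length(b$dwells),
    no_contacts = length(b$dwells) == 0
  )
}
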