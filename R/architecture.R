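# Domain architectures: ordered segment tables describing a protomer as rigid
# domains (with bead templates) joined by flexible linkers, plus the dimer
# contact rules used when assembling two protomers.

#' Define a protomer domain architecture
#'
#' An architecture is an ordered set of residue segments tiling `1..n_residues`
#' (a one-residue overlap is tolerated at segment boundaries, as in construct
#' definitions such as NT 1-86 / TPR 85-213 / CT 213-313). Rigid segments carry
#' a template reference resolved by [bead_template()]; flexible segments are
#' grown as self-avoiding chains.
#'
#' @param segments data frame with columns `name`, `start`, `end` (inclusive,
#'   1-based), `kind` (`"rigid"` or `"flexible"`) and `template_ref`
#'   (`NA` for flexible segments).
#' @param n_residues total protomer length.
#' @param dimer_contacts data frame with columns `domain`, `max_center_distance`
#'   (nm) and `mandatory` (logical). Exactly one mandatory contact (the
#'   N-terminal dimerization) is required for dimer building.
#' @return an object of class `domain_architecture`.
#' @export
domain_architecture <- function(segments, n_residues, dimer_contacts = NULL) {
  segments <- as.data.frame(segments)
  need <- c("name", "start", "end", "kind")
  if (!all(need %in% names(segments))) {
    stop("segments must have columns name, start, end, kind")
  }
  if (!"template_ref" %in% names(segments)) segments$template_ref <- NA_character_
  segments <- segments[order(segments$start), , drop = FALSE]
  if (!all(segments$kind %in% c("rigid", "flexible"))) {
    stop("segment kind must be 'rigid' or 'flexible'")
  }
  if (any(segments$end < segments$start)) stop("segment end before start")
  # tiling: no gaps, at most a one-residue overlap at boundaries
  if (segments$start[1] != 1) stop("segments must start at residue 1")
  if (segments$end[nrow(segments)] != n_residues) {
    stop("segments must end at residue n_residues")
  }
  if (nrow(segments) > 1) {
    step <- segments$start[-1] - segments$end[-nrow(segments)]
    if (any(step > 1)) stop("gap between segments")
    if (any(step < 0)) stop("segments overlap by more than one residue")
  }
  rigid <- segments$kind == "rigid"
  if (any(rigid & (is.na(segments$template_ref) | segments$template_ref == ""))) {
    stop("every rigid segment needs a template_ref")
  }
  if (any(!rigid & !is.na(segments$template_ref))) {
    stop("flexible segments must not carry a template_ref")
  }
  if (!is.null(dimer_contacts)) {
    dimer_contacts <- as.data.frame(dimer_contacts)
    stopifnot(all(c("domain", "max_center_distance", "mandatory") %in%
                    names(dimer_contacts)))
    if (!all(dimer_contacts$domain %in% segments$name)) {
      stop("dimer contact names an unknown segment")
    }
    if (sum(dimer_contacts$mandatory) > 1) {
      stop("at most one mandatory dimer contact is allowed")
    }
  }
  structure(
    list(segments = segments, n_residues = as.integer(n_residues),
         dimer_contacts = dimer_contacts),
    class = "domain_architecture"
  )
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat("Domain architecture:", x$n_residues, "residues\n")
  print(x$segments, row.names = FALSE)
  if (!is.null(x$dimer_contacts)) {
    cat("Dimer contacts:\n")
    print(x$dimer_contacts, row.names = FALSE)
  }
  invisible(x)
}

#' Default SGTA-like architecture
#'
#' A 313-residue protomer with a rigid N-terminal dimerization core (1-65), a
#' flexible NT-TPR linker (66-86), a rigid TPR domain (87-206), a short linker
#' (207-212), and a flexible C-terminal substrate-binding region (213-313)
#' modelled as dummy beads. The N-terminal contact is obligate; the C-terminal
#' contact is the switchable closure.
#'
#' @param contact_distance_nm centre-centre distance (nm) below which two
#'   homologous domains count as "in contact" (default 1.5).
#' @return a [domain_architecture()].
#' @export
sgta_architecture <- function(contact_distance_nm = 1.5) {
  segments <- data.frame(
    name = c("NT", "linker1", "TPR", "linker2", "CT"),
    start = c(1L, 66L, 87L, 207L, 213L),
    end = c(65L, 86L, 206L, 212L, 313L),
    kind = c("rigid", "flexible", "rigid", "flexible", "flexible"),
    template_ref = c("bundle", NA, "bundle", NA, NA),
    stringsAsFactors = FALSE
  )
  contacts <- data.frame(
    domain = c("NT", "CT"),
    max_center_distance = contact_distance_nm,
    mandatory = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  domain_architecture(segments, 313L, contacts)
}

#' Read a domain architecture from a YAML config
#'
#' Expects top-level keys `n_residues`, `segments` (list of maps with `name`,
#' `start`, `end`, `kind`, optional `template_ref`) and optional
#' `dimer_contacts` (list of maps with `domain`, `max_center_distance`,
#' `mandatory`).
#'
#' @param path YAML file path.
#' @return a [domain_architecture()].
#' @export
read_architecture_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  segs <- do.call(rbind, lapply(cfg$segments, function(s) {
    data.frame(name = s$name, start = s$start, end = s$end, kind = s$kind,
               template_ref = s$template_ref %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  contacts <- NULL
  if (!is.null(cfg$dimer_contacts)) {
    contacts <- do.call(rbind, lapply(cfg$dimer_contacts, function(ct) {
      data.frame(domain = ct$domain,
                 max_center_distance = ct$max_center_distance,
                 mandatory = isTRUE(ct$mandatory), stringsAsFactors = FALSE)
    }))
  }
  domain_architecture(segs, cfg$n_residues, contacts)
}

# ---- synthetic rigid templates -------------------------------------------

#' @keywords internal
ideal_helix <- function(n, radius = 0.23, twist_deg = 100, step = 0.38,
                        phase = 0) {
  # rise chosen so the consecutive-bead chord is exactly `step`
  chord_xy <- 2 * radius * sin(twist_deg * pi / 360)
  rise <- sqrt(step^2 - chord_xy^2)
  ang <- phase + (seq_len(n) - 1) * twist_deg * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), (seq_len(n) - 1) * rise)
}

#' @keywords internal
bridge_beads <- function(p0, p1, n, step = 0.38, out_dir = c(0, 0, 1)) {
  # n beads between anchors p0/p1 on a circular arc of n+1 equal chords
  d <- sqrt(sum((p1 - p0)^2))
  if ((n + 1) * step <= d) stop("bridge too short for gap")
  f <- function(th) sin((n + 1) * th) / sin(th) - d / step
  th <- stats::uniroot(f, c(1e-9, pi / (n + 1) - 1e-9), tol = 1e-14)$root
  phi <- 2 * (n + 1) * th
  R <- step / (2 * sin(th))
  u <- (p1 - p0) / d
  v <- out_dir - sum(out_dir * u) * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) {  # hint parallel to gap: pick any perpendicular
    v <- c(u[2] - u[3], u[3] - u[1], u[1] - u[2])
    nv <- sqrt(sum(v^2))
  }
  v <- v / nv
  mid <- (p0 + p1) / 2
  ctr <- mid - v * R * cos(phi / 2)
  ang <- -phi / 2 + (seq_len(n)) * 2 * th
  t(vapply(ang, function(a) ctr + R * (sin(a) * u + cos(a) * v),
           numeric(3)))
}

#' Synthetic rigid-domain bead template
#'
#' Deterministic idealized helical-bundle CA trace: ideal alpha-helix segments
#' (0.38 nm consecutive-bead spacing) laid antiparallel on a grid and joined by
#' equal-chord circular-arc turns. Serves as the rigid-body template for
#' coarse-grained domain placement; real crystallographic templates can be
#' substituted by passing explicit coordinates to the builders.
#'
#' @param ref template name; currently `"bundle"` (or `"bundle:<helix_len>"`).
#' @param n_residues number of beads the template must contain.
#' @return an `n_residues` x 3 coordinate matrix (nm).
#' @export
bead_template <- function(ref, n_residues) {
  if (!grepl("^bundle", ref)) stop("unknown template_ref: ", ref)
  helix_len <- 18L
  if (grepl(":", ref)) helix_len <- as.integer(sub("^bundle:", "", ref))
  turn_len <- 4L
  spacing <- 1.05
  n <- as.integer(n_residues)
  coords <- matrix(NA_real_, n, 3)
  placed <- 0L
  k <- 0L
  z_anchor <- 0
  while (placed < n) {
    k <- k + 1L
    remaining <- n - placed
    m <- min(helix_len, remaining)
    row <- (k - 1L) %/% 3L
    ci <- (k - 1L) %% 3L
    if (row %% 2L == 1L) ci <- 2L - ci     # serpentine: consecutive helices adjacent
    col_xy <- c(ci * spacing, row * spacing)
    prev_xy <- if (k > 1L) coords[placed, 1:2] else col_xy + c(spacing, 0)
    # start bead faces the previous helix; shortens and de-tangles the turn
    phase <- atan2(prev_xy[2] - col_xy[2], prev_xy[1] - col_xy[1])
    up <- k %% 2L == 1L
    h <- ideal_helix(m, phase = phase)
    if (!up) h[, 3] <- -h[, 3]                    # antiparallel
    h[, 1] <- h[, 1] + col_xy[1]
    h[, 2] <- h[, 2] + col_xy[2]
    h[, 3] <- h[, 3] + z_anchor
    if (k > 1L) {
      # join previous helix end to this helix start by an arc routed past the
      # helix ends (bulging beyond the previous helix's direction of travel)
      gap_n <- min(turn_len, remaining)
      p0 <- coords[placed, ]
      p1 <- h[1, ]
      out_hint <- c(0, 0, if (up) -1 else 1)  # previous helix travelled this way
      arc <- bridge_beads(p0, p1, gap_n, out_dir = out_hint)
      take <- min(gap_n, n - placed)
      coords[placed + seq_len(take), ] <- arc[seq_len(take), , drop = FALSE]
      placed <- placed + take
      if (placed >= n) break
      m2 <- min(nrow(h), n - placed)
      coords[placed + seq_len(m2), ] <- h[seq_len(m2), , drop = FALSE]
      placed <- placed + m2
    } else {
      coords[seq_len(m), ] <- h[seq_len(m), , drop = FALSE]
      placed <- m
    }
    z_anchor <- coords[placed, 3]
  }
  coords <- coords - matrix(colMeans(coords), n, 3, byrow = TRUE)
  coords
}
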