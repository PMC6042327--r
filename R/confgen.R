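# Conformer generation: rigid domain templates placed by random rigid
# transforms, flexible segments grown as self-avoiding chains with fixed
# 0.38 nm steps, dimers assembled under an obligate N-terminal contact and an
# optional (switchable) C-terminal closure contact.

SAW_STEP <- 0.38
CLASH_CUTOFF <- 0.34

#' @keywords internal
growth_failure <- function(msg) {
  stop(errorCondition(msg, class = c("saw_growth_failure", "error")))
}

#' @keywords internal
constraint_failure <- function(msg) {
  stop(errorCondition(msg, class = c("constraint_failure", "error")))
}

# distance from point p to each row of mat
#' @keywords internal
dist_to <- function(mat, p) {
  sqrt((mat[, 1] - p[1])^2 + (mat[, 2] - p[2])^2 + (mat[, 3] - p[3])^2)
}

#' @keywords internal
grow_saw <- function(n, prev, existing, step = SAW_STEP,
                     clash = CLASH_CUTOFF, bias_target = NULL,
                     bias_weight = 0, bias_free_radius = 1.4,
                     max_retry = 300, max_backtracks = 60,
                     backtrack_depth = 8) {
  # grows n beads starting bonded to `prev`; `existing` holds all placed beads
  # (including prev as its last row); returns the n new coordinates.
  # When a bias target is set the walk is steered towards it while outside
  # `bias_free_radius`, and wanders freely once inside, so the grown segment
  # clusters around the target (closed-state rendezvous growth). Dead ends are
  # escaped by backtracking a few beads before the growth-failure error fires.
  ne <- nrow(existing)
  pts <- rbind(existing, matrix(NA_real_, n, 3))
  g <- 0L
  backtracks <- 0L
  while (g < n) {
    cur <- if (g == 0L) prev else pts[ne + g, ]
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      dir <- as.numeric(random_unit_vector())
      if (!is.null(bias_target) && bias_weight > 0) {
        to <- bias_target - cur
        nt <- sqrt(sum(to^2))
        if (nt > bias_free_radius && nt > 1e-9) {
          dir <- (1 - bias_weight) * dir + bias_weight * to / nt
          dir <- dir / sqrt(sum(dir^2))
        }
      }
      cand <- cur + step * dir
      # candidate is adjacent only to `cur` (= last placed bead)
      last <- ne + g
      if (last > 1L) {
        d <- dist_to(pts[seq_len(last - 1L), , drop = FALSE], cand)
        if (min(d) < clash) next
      }
      ok <- TRUE
      break
    }
    if (ok) {
      g <- g + 1L
      pts[ne + g, ] <- cand
    } else {
      backtracks <- backtracks + 1L
      if (backtracks > max_backtracks || g == 0L) growth_failure(sprintf(
        "self-avoiding growth failed at bead %d of %d (%d backtracks)",
        g + 1L, n, backtracks))
      g <- max(0L, g - backtrack_depth)
    }
  }
  pts[ne + seq_len(n), , drop = FALSE]
}

#' @keywords internal
place_rigid <- function(template, prev = NULL, existing = NULL,
                        center_target = NULL, step = SAW_STEP,
                        clash = CLASH_CUTOFF, max_retry = 200) {
  # random rigid transform of `template`; either bonded to `prev` via its
  # first bead, or centred on `center_target` (free placement)
  for (try in seq_len(max_retry)) {
    R <- random_rotation()
    if (!is.null(center_target)) {
      ctr <- colMeans(template)
      coords <- sweep(template, 2, ctr) %*% t(R)
      coords <- sweep(coords, 2, center_target, "+")
    } else if (!is.null(prev)) {
      dir <- as.numeric(random_unit_vector())
      first <- prev + step * dir
      coords <- sweep(template, 2, template[1, ]) %*% t(R)
      coords <- sweep(coords, 2, first, "+")
    } else {
      coords <- template %*% t(R)
    }
    if (!is.null(existing) && nrow(existing) > 0) {
      # first template bead is bonded to prev (last existing row) when chained
      skip_last <- !is.null(prev)
      ref <- if (skip_last) existing[-nrow(existing), , drop = FALSE] else existing
      ok <- TRUE
      if (nrow(ref) > 0 && min(pracma::distmat(coords, ref)) < clash) ok <- FALSE
      if (ok && skip_last && nrow(coords) > 1) {
        # beads 2..n of the template are non-adjacent to prev
        if (min(dist_to(coords[-1, , drop = FALSE],
                        existing[nrow(existing), ])) < clash) ok <- FALSE
      }
      if (!ok) next
    }
    return(coords)
  }
  growth_failure("rigid-body placement failed: no clash-free pose found")
}

#' @keywords internal
segment_plan <- function(arch) {
  segs <- arch$segments
  last <- 0L
  plan <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    start_eff <- max(segs$start[i], last + 1L)
    plan[[i]] <- list(name = segs$name[i], kind = segs$kind[i],
                      template_ref = segs$template_ref[i],
                      start = segs$start[i], end = segs$end[i],
                      start_eff = start_eff,
                      resnos = seq.int(start_eff, segs$end[i]))
    last <- segs$end[i]
  }
  plan
}

#' Build a single coarse-grained protomer
#'
#' Rigid segments are random rigid transforms of their templates; flexible
#' segments are self-avoiding chains with fixed 0.38 nm steps. Fails with a
#' `saw_growth_failure` error (never a silent partial chain) if no clash-free
#' continuation exists within the retry budget.
#'
#' @param arch a [domain_architecture()].
#' @param rng_seed integer seed, or `NULL` to continue the caller's RNG stream.
#' @param protomer protomer id for the emitted beads.
#' @param existing optional coordinate matrix of already-placed beads (the
#'   partner protomer) to avoid.
#' @param anchor_center optional target for the geometric centre of the first
#'   (rigid) segment; used when assembling dimers.
#' @param bias optional list `list(domain=, target=, weight=)` biasing the
#'   growth direction of one flexible segment towards a point (closed-state
#'   rendezvous).
#' @param templates optional named list of explicit template coordinate
#'   matrices overriding [bead_template()] per segment name.
#' @param first_segment_coords optional pre-placed coordinates for the first
#'   segment (used by [build_dimer()] to position the partner protomer's
#'   dimerization domain before growing the rest of the chain).
#' @param stop_after optional segment name: build only up to (and including)
#'   this segment; the remaining segments can be grown later with
#'   [grow_remaining_segments()].
#' @return a single-protomer [bead_model()].
#' @export
build_protomer <- function(arch, rng_seed = NULL, protomer = "A",
                           existing = NULL, anchor_center = NULL,
                           bias = NULL, templates = NULL,
                           first_segment_coords = NULL, stop_after = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  plan <- segment_plan(arch)
  if (!is.null(stop_after)) {
    keep <- seq_len(match(stop_after, vapply(plan, `[[`, "", "name")))
    plan <- plan[keep]
  }
  coords <- matrix(numeric(0), 0, 3)
  all_pts <- existing %||% matrix(numeric(0), 0, 3)
  domains <- character(0)
  resnos <- integer(0)
  for (i in seq_along(plan)) {
    sg <- plan[[i]]
    prev <- if (nrow(coords) > 0) coords[nrow(coords), ] else NULL
    if (i == 1L && !is.null(first_segment_coords)) {
      new <- first_segment_coords
      if (nrow(new) != length(sg$resnos)) {
        stop("first_segment_coords has wrong number of beads")
      }
    } else if (sg$kind == "rigid") {
      tpl <- templates[[sg$name]] %||%
        bead_template(sg$template_ref, sg$end - sg$start + 1L)
      tpl <- tpl[(sg$start_eff - sg$start + 1L):nrow(tpl), , drop = FALSE]
      new <- if (is.null(prev)) {
        place_rigid(tpl, existing = all_pts,
                    center_target = anchor_center %||% c(0, 0, 0))
      } else {
        place_rigid(tpl, prev = prev, existing = all_pts)
      }
    } else {
      bt <- NULL; bw <- 0
      if (!is.null(bias) && identical(bias$domain, sg$name)) {
        bt <- bias$target; bw <- bias$weight %||% 0.6
      }
      if (is.null(prev)) {
        first <- anchor_center %||% c(0, 0, 0)
        rest <- grow_saw(length(sg$resnos) - 1L, prev = first,
                         existing = rbind(all_pts, first),
                         bias_target = bt, bias_weight = bw)
        new <- rbind(first, rest)
      } else {
        new <- grow_saw(length(sg$resnos), prev = prev, existing = all_pts,
                        bias_target = bt, bias_weight = bw)
      }
    }
    coords <- rbind(coords, new)
    all_pts <- rbind(all_pts, new)
    domains <- c(domains, rep(sg$name, length(sg$resnos)))
    resnos <- c(resnos, sg$resnos)
  }
  bead_model(
    data.frame(protomer = protomer, resno = resnos,
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               domain = domains, weight = 1, stringsAsFactors = FALSE),
    provenance = list(seed = rng_seed %||% NA_integer_, closed = NA)
  )
}

#' Grow the remaining segments of a partially built protomer
#'
#' Continues a chain built with `stop_after`, avoiding all beads in `existing`
#' (typically both protomers assembled so far).
#'
#' @param partial_beads the protomer's beads so far (data frame).
#' @param arch the architecture.
#' @param existing coordinate matrix of every placed bead (all protomers);
#'   its last row must be the protomer's current chain end.
#' @param bias optional `list(domain=, target=, weight=)` growth bias.
#' @param templates optional template override list.
#' @return data frame of new beads for this protomer.
#' @keywords internal
grow_remaining_segments <- function(partial_beads, arch, existing,
                                    bias = NULL, templates = NULL) {
  plan <- segment_plan(arch)
  done <- max(partial_beads$resno)
  protomer <- partial_beads$protomer[1]
  plan <- Filter(function(sg) sg$resnos[length(sg$resnos)] > done, plan)
  prev <- as.numeric(partial_beads[nrow(partial_beads), c("x", "y", "z")])
  all_pts <- existing
  out <- NULL
  for (sg in plan) {
    resnos <- sg$resnos[sg$resnos > done]
    if (sg$kind == "rigid") {
      tpl <- templates[[sg$name]] %||%
        bead_template(sg$template_ref, sg$end - sg$start + 1L)
      tpl <- tpl[(nrow(tpl) - length(resnos) + 1L):nrow(tpl), , drop = FALSE]
      new <- place_rigid(tpl, prev = prev, existing = all_pts)
    } else {
      bt <- NULL; bw <- 0; bfr <- 2.0
      if (!is.null(bias) && identical(bias$domain, sg$name)) {
        bt <- bias$target; bw <- bias$weight %||% 0.6
        bfr <- bias$free_radius %||% 2.0
      }
      new <- grow_saw(length(resnos), prev = prev, existing = all_pts,
                      bias_target = bt, bias_weight = bw,
                      bias_free_radius = bfr, max_backtracks = 30)
    }
    out <- rbind(out, data.frame(
      protomer = protomer, resno = resnos, x = new[, 1], y = new[, 2],
      z = new[, 3], domain = sg$name, weight = 1, stringsAsFactors = FALSE))
    all_pts <- rbind(all_pts, new)
    prev <- new[nrow(new), ]
  }
  out
}

#' Build an open or closed two-protomer dimer
#'
#' Both chains are first built through the segment preceding the closure
#' domain: protomer A from scratch, then protomer B with its first rigid
#' domain slid in along a random direction until just clash-free of A (and
#' accepted only inside the mandatory contact distance). The two C-terminal
#' flexible segments are then grown last. In the closed state they are steered
#' towards a mutual rendezvous point between the two chain ends and the
#' conformer is accepted only if the two C-terminal segment centres fall
#' within the contact distance; rejected conformers are rebuilt from scratch,
#' so closure genuinely conditions the whole dimer geometry (chains whose
#' central domains drifted apart rarely close).
#'
#' @param arch a [domain_architecture()] with one mandatory dimer contact.
#' @param closed logical: enforce the optional (C-terminal) contact.
#' @param rng_seed integer seed.
#' @param max_attempts dimer-level rebuild budget.
#' @param ct_bias_weight growth-direction bias towards the rendezvous (0..1).
#' @param templates optional template override list (see [build_protomer()]).
#' @return a two-protomer [bead_model()].
#' @export
build_dimer <- function(arch, closed = FALSE, rng_seed = NULL,
                        max_attempts = 80, ct_bias_weight = 0.6,
                        templates = NULL) {
  contacts <- arch$dimer_contacts
  if (is.null(contacts) || sum(contacts$mandatory) != 1) {
    constraint_failure("dimer building needs exactly one mandatory contact")
  }
  mand <- contacts[contacts$mandatory, , drop = FALSE]
  opt <- contacts[!contacts$mandatory, , drop = FALSE]
  if (closed && nrow(opt) == 0) {
    constraint_failure("closed state requested but no optional contact defined")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  first_seg <- arch$segments$name[1]
  if (mand$domain[1] != first_seg) {
    constraint_failure(paste0("mandatory contact must be the first segment (",
                              first_seg, "), got ", mand$domain[1]))
  }
  seg1 <- arch$segments[1, ]
  tpl1 <- templates[[seg1$name]] %||%
    bead_template(seg1$template_ref, seg1$end - seg1$start + 1L)
  segs <- arch$segments
  # the closure domain (last segment) is grown after both chains exist
  tail_name <- segs$name[nrow(segs)]
  stop_name <- segs$name[nrow(segs) - 1L]
  if (closed && opt$domain[1] != tail_name) {
    constraint_failure("the optional (closure) contact must be the last segment")
  }
  for (attempt in seq_len(max_attempts)) {
    a <- tryCatch(
      build_protomer(arch, protomer = "A", templates = templates,
                     stop_after = stop_name),
      saw_growth_failure = function(e) NULL)
    if (is.null(a)) next
    ca <- domain_center(a, mand$domain[1], "A")
    # slide a randomly oriented copy of the dimerization domain in along a
    # random direction until just clash-free; accept if inside the contact cut
    seg1_b <- NULL
    xyz_a <- bm_coords(a)
    dsteps <- seq(0.4, 0.98, by = 0.04) * mand$max_center_distance[1]
    m1 <- nrow(tpl1)
    for (pose in 1:80) {
      R <- random_rotation()
      u <- as.numeric(random_unit_vector())
      rot <- sweep(tpl1, 2, colMeans(tpl1)) %*% t(R)
      # evaluate every slide offset in one distance-matrix call
      stacked <- rot[rep(seq_len(m1), length(dsteps)), ] +
        (rep(dsteps, each = m1) %o% u) +
        matrix(ca, m1 * length(dsteps), 3, byrow = TRUE)
      dmin <- apply(matrix(apply(pracma::distmat(stacked, xyz_a), 1, min),
                           m1), 2, min)
      hit <- which(dmin >= CLASH_CUTOFF)
      if (length(hit) > 0) {
        d <- dsteps[hit[1]]
        seg1_b <- sweep(rot, 2, ca + d * u, "+")
        break
      }
    }
    if (is.null(seg1_b)) next
    b <- tryCatch(
      build_protomer(arch, protomer = "B", existing = xyz_a,
                     first_segment_coords = seg1_b, templates = templates,
                     stop_after = stop_name),
      saw_growth_failure = function(e) NULL)
    if (is.null(b)) next
    end_a <- as.numeric(a$beads[nrow(a$beads), c("x", "y", "z")])
    end_b <- as.numeric(b$beads[nrow(b$beads), c("x", "y", "z")])
    xyz_b <- bm_coords(b)
    # grow the two closure tails last; retry tails a few times per base before
    # rebuilding the whole dimer, so closure still conditions base geometry
    for (tail_try in 1:4) {
      bias <- NULL
      if (closed) {
        # the C-terminal dimer forms away from the N-terminal dimer, closing
        # the molecule into a ring rather than collapsing it onto itself
        nt_ctr <- (domain_center(a, mand$domain[1], "A") +
                     domain_center(b, mand$domain[1], "B")) / 2
        mid <- (end_a + end_b) / 2
        away <- mid - nt_ctr
        na_ <- sqrt(sum(away^2))
        away <- if (na_ > 1e-6) away / na_ else as.numeric(random_unit_vector())
        rendezvous <- mid + 1.5 * away +
          0.5 * as.numeric(random_unit_vector())
        bias <- list(domain = tail_name, target = rendezvous,
                     weight = ct_bias_weight)
      }
      tail_a <- tryCatch(
        grow_remaining_segments(a$beads, arch, existing = rbind(xyz_b, xyz_a),
                                bias = bias, templates = templates),
        saw_growth_failure = function(e) NULL)
      if (is.null(tail_a)) next
      xyz_ta <- as.matrix(tail_a[, c("x", "y", "z")])
      tail_b <- tryCatch(
        grow_remaining_segments(b$beads, arch,
                                existing = rbind(xyz_a, xyz_ta, xyz_b),
                                bias = bias, templates = templates),
        saw_growth_failure = function(e) NULL)
      if (is.null(tail_b)) next
      model <- bead_model(rbind(a$beads, tail_a, b$beads, tail_b),
                          provenance = list(seed = rng_seed %||% NA_integer_,
                                            closed = closed))
      if (closed) {
        dd <- sqrt(sum((domain_center(model, opt$domain[1], "A") -
                          domain_center(model, opt$domain[1], "B"))^2))
        if (dd > opt$max_center_distance[1]) next
      }
      return(model)
    }
  }
  constraint_failure(sprintf(
    "could not satisfy %s contact within %d attempts",
    if (closed) opt$domain[1] else mand$domain[1], max_attempts))
}

#' Generate a pool of dimer conformers
#'
#' The closed/open label of each conformer is a Bernoulli draw with probability
#' `fraction_closed`, realized under `rng_seed`; conformer `i` is then built
#' under the derived stream seed [seed_stream()]`(rng_seed, i)`, so pools are
#' reproducible bit-for-bit and individual conformers can be regenerated in
#' isolation.
#'
#' @param arch a [domain_architecture()].
#' @param n pool size (the study-scale default is 10000; tests and examples use
#'   much smaller pools).
#' @param fraction_closed probability that a conformer is built closed.
#' @param rng_seed integer seed.
#' @param templates optional template override list.
#' @return object of class `conformer_pool` with fields `conformers`, `rg`,
#'   `closed`, `fraction_closed`, `seed`.
#' @export
generate_pool <- function(arch, n = 10000, fraction_closed = 0, rng_seed = 1,
                          templates = NULL) {
  stopifnot(n >= 1, fraction_closed >= 0, fraction_closed <= 1)
  set.seed(rng_seed)
  flags <- stats::runif(n) < fraction_closed
  if (is.null(templates)) {
    # resolve templates once: identical rigid bodies across the pool
    segs <- arch$segments
    templates <- list()
    for (i in which(segs$kind == "rigid")) {
      templates[[segs$name[i]]] <-
        bead_template(segs$template_ref[i], segs$end[i] - segs$start[i] + 1L)
    }
  }
  conformers <- vector("list", n)
  for (i in seq_len(n)) {
    conformers[[i]] <- build_dimer(arch, closed = flags[i],
                                   rng_seed = seed_stream(rng_seed, i),
                                   templates = templates)
  }
  structure(
    list(conformers = conformers,
         rg = vapply(conformers, radius_of_gyration, numeric(1)),
         closed = flags, fraction_closed = fraction_closed, seed = rng_seed),
    class = "conformer_pool"
  )
}

#' @export
print.conformer_pool <- function(x, ...) {
  cat("Conformer pool:", length(x$conformers), "dimers;",
      sum(x$closed), "closed; Rg", signif(mean(x$rg), 4), "+/-",
      signif(stats::sd(x$rg), 3), "nm (seed", x$seed, ")\n")
  invisible(x)
}

#' Spin-label site
#'
#' @param residue_index residue carrying the (CA-modelled) nitroxide label.
#' @param name site name, e.g. `"S197C"`.
#' @return object of class `spin_label_site`.
#' @export
spin_label_site <- function(residue_index, name = paste0("r", residue_index)) {
  stopifnot(residue_index >= 1)
  structure(list(residue_index = as.integer(residue_index), name = name),
            class = "spin_label_site")
}

#' Distance between homologous labelled sites of a dimer (nm)
#'
#' @param model a two-protomer [bead_model()].
#' @param site a [spin_label_site()] or residue index.
#' @return Euclidean distance in nm.
#' @export
interlabel_distance <- function(model, site) {
  idx <- if (inherits(site, "spin_label_site")) site$residue_index else
    as.integer(site)
  b <- model$beads
  pa <- b[b$protomer == "A" & b$resno == idx, c("x", "y", "z")]
  pb <- b[b$protomer == "B" & b$resno == idx, c("x", "y", "z")]
  if (nrow(pa) != 1 || nrow(pb) != 1) {
    stop(errorCondition(paste("residue", idx, "absent from one or both protomers"),
                        class = c("missing_site", "error")))
  }
  sqrt(sum((as.numeric(pa) - as.numeric(pb))^2))
}
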