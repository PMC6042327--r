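# Conformer generator: templates, protomer/dimer builders, pools, label sites.

test_that("architecture validation enforces tiling, templates and contacts", {
  segs <- data.frame(name = c("a", "b"), start = c(1, 11), end = c(10, 20),
                     kind = c("rigid", "flexible"),
                     template_ref = c("bundle", NA))
  expect_s3_class(domain_architecture(segs, 20), "domain_architecture")

  # one-residue construct-style overlap is allowed
  segs_ov <- segs; segs_ov$start[2] <- 10
  expect_s3_class(domain_architecture(segs_ov, 20), "domain_architecture")

  segs_gap <- segs; segs_gap$start[2] <- 12
  expect_error(domain_architecture(segs_gap, 20), "gap")
  segs_ov2 <- segs; segs_ov2$start[2] <- 9
  expect_error(domain_architecture(segs_ov2, 20), "overlap")
  segs_tpl <- segs; segs_tpl$template_ref[1] <- NA
  expect_error(domain_architecture(segs_tpl, 20), "template_ref")

  contacts <- data.frame(domain = c("a", "b"), max_center_distance = 1.5,
                         mandatory = c(TRUE, TRUE))
  expect_error(domain_architecture(segs, 20, contacts), "mandatory")
})

test_that("architecture YAML round trip preserves the segment table", {
  arch <- shared_arch()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    n_residues = arch$n_residues,
    segments = lapply(seq_len(nrow(arch$segments)), function(i) {
      s <- arch$segments[i, ]
      out <- list(name = s$name, start = s$start, end = s$end, kind = s$kind)
      if (!is.na(s$template_ref)) out$template_ref <- s$template_ref
      out
    }),
    dimer_contacts = lapply(seq_len(nrow(arch$dimer_contacts)), function(i) {
      ct <- arch$dimer_contacts[i, ]
      list(domain = ct$domain, max_center_distance = ct$max_center_distance,
           mandatory = ct$mandatory)
    })
  ), path)
  arch2 <- read_architecture_yaml(path)
  expect_equal(arch2$segments$name, arch$segments$name)
  expect_equal(arch2$segments$start, arch$segments$start)
  expect_equal(arch2$dimer_contacts$mandatory, arch$dimer_contacts$mandatory)
})

test_that("synthetic templates satisfy bond and clash geometry", {
  for (n in c(65L, 120L)) {
    tpl <- bead_template("bundle", n)
    expect_equal(nrow(tpl), n)
    bonds <- sqrt(rowSums(diff(tpl)^2))
    expect_true(all(abs(bonds - 0.38) < 0.01))
    dm <- as.matrix(dist(tpl))
    dm[abs(row(dm) - col(dm)) <= 1] <- Inf
    expect_gte(min(dm), 0.34)
  }
})

test_that("a lone rigid segment is a rigid transform of its template", {
  segs <- data.frame(name = "dom", start = 1, end = 40, kind = "rigid",
                     template_ref = "bundle")
  arch <- domain_architecture(segs, 40)
  tpl <- bead_template("bundle", 40)
  p <- build_protomer(arch, rng_seed = 7)
  xyz <- as.matrix(p$beads[, c("x", "y", "z")])
  # internal pairwise distances identical to the template (rigid invariance)
  expect_lt(max(abs(dist(xyz) - dist(tpl))), 1e-9)
})

test_that("all-flexible chains have exact bonds and no clashes", {
  segs <- data.frame(name = "tail", start = 1, end = 100, kind = "flexible",
                     template_ref = NA)
  arch <- domain_architecture(segs, 100)
  p <- build_protomer(arch, rng_seed = 3)
  xyz <- as.matrix(p$beads[, c("x", "y", "z")])
  bonds <- sqrt(rowSums(diff(xyz)^2))
  expect_true(all(abs(bonds - 0.38) < 1e-9))
  dm <- as.matrix(dist(xyz))
  dm[abs(row(dm) - col(dm)) <= 1] <- Inf
  expect_gte(min(dm), 0.34)
  expect_true(check_bead_model(p))
})

test_that("chain growth matches an independent self-avoiding-walk sampler", {
  # oracle: plain rejection SAW with identical step and clash parameters
  oracle_saw <- function(n, seed) {
    set.seed(seed)
    e2e <- numeric(0)
    while (length(e2e) < n) {
      pts <- matrix(0, 50, 3)
      ok <- TRUE
      for (i in 2:50) {
        placed <- FALSE
        for (try in 1:200) {
          v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
          cand <- pts[i - 1, ] + 0.38 * v
          d <- sqrt(rowSums(sweep(pts[seq_len(i - 2), , drop = FALSE], 2,
                                  cand)^2))
          if (i > 2 && min(d) < 0.34) next
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
        pts[i, ] <- cand
      }
      if (ok) e2e <- c(e2e, sum((pts[50, ] - pts[1, ])^2))
    }
    mean(e2e)
  }
  segs <- data.frame(name = "tail", start = 1, end = 50, kind = "flexible",
                     template_ref = NA)
  arch <- domain_architecture(segs, 50)
  set.seed(501)
  impl <- mean(vapply(seq_len(4000), function(i) {
    p <- build_protomer(arch)
    xyz <- as.matrix(p$beads[, c("x", "y", "z")])
    sum((xyz[50, ] - xyz[1, ])^2)
  }, numeric(1)))
  orac <- oracle_saw(4000, seed = 502)
  expect_lt(abs(impl - orac) / orac, 0.05)
})

test_that("open dimers satisfy the mandatory contact and leave the tail free", {
  arch <- shared_arch()
  pool <- shared_pool("open", 40)
  cutoff <- arch$dimer_contacts$max_center_distance[1]
  nt_d <- vapply(pool$conformers, function(m)
    sqrt(sum((domain_center(m, "NT", "A") - domain_center(m, "NT", "B"))^2)),
    numeric(1))
  ct_d <- vapply(pool$conformers, function(m)
    sqrt(sum((domain_center(m, "CT", "A") - domain_center(m, "CT", "B"))^2)),
    numeric(1))
  expect_true(all(nt_d <= cutoff))
  expect_gte(mean(ct_d > cutoff), 0.5)
})

test_that("closed dimers satisfy both contacts in every model", {
  arch <- shared_arch()
  pool <- shared_pool("closed", 40)
  cutoff <- arch$dimer_contacts$max_center_distance[1]
  for (m in pool$conformers) {
    expect_lte(sqrt(sum((domain_center(m, "NT", "A") -
                           domain_center(m, "NT", "B"))^2)), cutoff)
    expect_lte(sqrt(sum((domain_center(m, "CT", "A") -
                           domain_center(m, "CT", "B"))^2)), cutoff)
  }
})

test_that("every pooled conformer satisfies bond and clash invariants", {
  for (kind in c("open", "closed")) {
    pool <- shared_pool(kind, 40)
    for (m in pool$conformers[seq(1, 40, by = 4)]) {
      expect_true(check_bead_model(m))
    }
  }
})

test_that("closure pulls the central domains together on average", {
  tpr_d <- function(pool) vapply(pool$conformers, function(m)
    sqrt(sum((domain_center(m, "TPR", "A") - domain_center(m, "TPR", "B"))^2)),
    numeric(1))
  expect_lt(mean(tpr_d(shared_pool("closed", 40))),
            mean(tpr_d(shared_pool("open", 40))))
})

test_that("rigid segments keep template-identical internal distances", {
  tpl <- bead_template("bundle", 120)
  for (m in shared_pool("open", 40)$conformers[c(1, 9, 23)]) {
    b <- m$beads
    sel <- b$domain == "TPR" & b$protomer == "A"
    xyz <- as.matrix(b[sel, c("x", "y", "z")])
    expect_lt(max(abs(dist(xyz) - dist(tpl))), 1e-9)
  }
})

test_that("dimer building without a mandatory contact fails loudly", {
  arch <- shared_arch()
  arch$dimer_contacts$mandatory <- c(FALSE, FALSE)
  expect_error(build_dimer(arch, rng_seed = 1), class = "constraint_failure")
})

test_that("pools are reproducible, sized and labelled as requested", {
  arch <- shared_arch()
  p1 <- generate_pool(arch, 4, 0.5, rng_seed = 99)
  p2 <- generate_pool(arch, 4, 0.5, rng_seed = 99)
  expect_equal(length(p1$conformers), 4)
  expect_true(all(p1$rg > 0))
  expect_identical(p1$closed, p2$closed)
  for (i in 1:4) {
    expect_identical(p1$conformers[[i]]$beads, p2$conformers[[i]]$beads)
  }
  # stored Rg equals the mass-weighted second moment recomputed from scratch
  for (i in 1:4) {
    expect_equal(p1$rg[i], radius_of_gyration(p1$conformers[[i]]),
                 tolerance = 1e-12)
  }
  # closed-count draw matches the binomial realization under the seed
  pool <- shared_pool("mixed", 60)
  expect_true(sum(pool$closed) >= 17 && sum(pool$closed) <= 43)  # 99.9% band
})

test_that("interlabel distances are exact and respond to closure", {
  # mirror-symmetric pair 2.5 nm either side of a plane
  b <- data.frame(protomer = c("A", "B"), resno = 1,
                  x = c(-2.5, 2.5), y = 0, z = 0, domain = "d", weight = 1)
  expect_equal(interlabel_distance(bead_model(b), 1), 5.0)

  m <- shared_pool("open", 40)$conformers[[2]]
  site <- spin_label_site(197, "S197C")
  pa <- unlist(m$beads[m$beads$protomer == "A" & m$beads$resno == 197,
                       c("x", "y", "z")])
  pb <- unlist(m$beads[m$beads$protomer == "B" & m$beads$resno == 197,
                       c("x", "y", "z")])
  expect_equal(interlabel_distance(m, site), sqrt(sum((pa - pb)^2)),
               tolerance = 1e-12)
  expect_error(interlabel_distance(m, 9999), class = "missing_site")

  d197 <- function(pool) vapply(pool$conformers, interlabel_distance,
                                numeric(1), site = site)
  expect_gt(mean(d197(shared_pool("open", 40))),
            mean(d197(shared_pool("closed", 40))))
})

test_that("bead models and pools round-trip through PDB + manifest", {
  m <- shared_pool("open", 40)$conformers[[1]]
  path <- tempfile(fileext = ".pdb")
  write_beadmodel_pdb(m, path)
  m2 <- read_beadmodel_pdb(path, arch = shared_arch())
  expect_equal(nrow(m2$beads), nrow(m$beads))
  # PDB stores Angstroms at 1e-3 A precision -> 1e-4 nm
  for (col in c("x", "y", "z")) {
    expect_lt(max(abs(sort(m2$beads[[col]]) - sort(m$beads[[col]]))), 2e-4)
  }
  expect_setequal(unique(m2$beads$domain), unique(m$beads$domain))

  pool <- generate_pool(shared_arch(), 3, 1, rng_seed = 17)
  dir <- tempfile()
  write_pool(pool, dir)
  pool2 <- read_pool(dir, arch = shared_arch())
  expect_equal(length(pool2$conformers), 3)
  expect_equal(pool2$rg, pool$rg, tolerance = 1e-6)
  expect_equal(pool2$closed, pool$closed)
})
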