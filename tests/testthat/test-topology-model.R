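test_that("critical points classify by rank and signature", {
  expect_identical(classify_critical_point(c(-2, -1, 5)),
                   list(rank = 3L, signature = -1L, label = "BCP"))
  expect_identical(classify_critical_point(c(-3, -1.5, -0.2)),
                   list(rank = 3L, signature = -3L, label = "NACP"))
  expect_identical(classify_critical_point(c(-1, 0, 1), zero_tol = 1e-10),
                   list(rank = 2L, signature = 0L, label = "degenerate"))
  expect_identical(classify_critical_point(c(0.5, 1, 2))$label, "CCP")
  expect_identical(classify_critical_point(c(-2, 1, 2))$label, "RCP")
  expect_error(classify_critical_point(c(-1, NaN, 1)), "finite")
  expect_error(classify_critical_point(c(1, 0, -1)), "ascending")
  expect_error(classify_critical_point(c(-1, 0, 1), zero_tol = 0), "zero_tol")
})

test_that("classification satisfies the rank/signature invariants on random input", {
  set.seed(7)
  for (i in 1:500) {
    ev <- sort(stats::rnorm(3))
    if (stats::runif(1) < 0.3) ev[sample(3, 1)] <- 0
    ev <- sort(ev)
    cls <- classify_critical_point(ev, zero_tol = 1e-8)
    expect_lte(abs(cls$signature), cls$rank)
    expect_identical((cls$signature - cls$rank) %% 2L, 0L)
    expect_identical(cls$rank == 3L, cls$label != "degenerate")
  }
})

test_that("the Poincare-Hopf residual is the alternating census sum", {
  expect_identical(poincare_hopf_residual(1, 0, 0, 0), 1L)
  expect_identical(poincare_hopf_residual(12, 12, 1, 0), 1L)
  expect_identical(poincare_hopf_residual(22, 24, 4, 1), 1L)
  expect_identical(poincare_hopf_residual(4, 4, 0, 0), 0L)
  expect_error(poincare_hopf_residual(-1, 0, 0, 0), "non-negative")
  expect_error(poincare_hopf_residual(1.5, 0, 0, 0), "integer")
})

test_that("constructors enforce the model invariants", {
  expect_error(critical_point(c(0, 0, 0), rank = 3, signature = 2),
               "parity")
  expect_error(critical_point(c(0, 0, 0), rank = 2, signature = -3),
               "exceed")
  expect_error(critical_point(c(0, 0, 0), rank = 3, signature = -1,
                              eigenvalues = c(-2, -1, -0.5)),
               "inconsistent")
  expect_error(qct_point(c(0, 0, Inf)), "finite")
  expect_error(qct_point(c(0, 0, 0), scalars = c(rho = NA_real_)), "finite")
  expect_error(nucleus("Xx", c(0, 0, 0), 0), "unrecognized")
  expect_error(gradient_path(rbind(c(0, 0, 0), c(0, 0, 0)), 1, 2),
               "distinct")
  expect_error(qct_ring(c(1, 2), 5), "at least 3")
  expect_error(qct_cage(1, 5), "at least 2")
  expect_error(triangulation(diag(3), faces = rbind(c(1, 1, 2))), "distinct")
  expect_error(triangulation(diag(3), faces = rbind(c(1, 2, 4))), "range")
})

test_that("an AIL requires two paths sharing its BCP with distinct far ends", {
  pts <- function(a, b) rbind(a, (a + b) / 2, b)
  nacp <- function(p) critical_point(p, 3, -3)
  bcp <- function(p) critical_point(p, 3, -1,
                                    eigenvalues = c(-1, -0.5, 2),
                                    eigenvectors = diag(3))
  cps <- list(nacp(c(-1, 0, 0)), nacp(c(1, 0, 0)), bcp(c(0, 0, 0)))
  p1 <- gradient_path(pts(c(0, 0, 0), c(-1, 0, 0)), 3, 1)
  p2 <- gradient_path(pts(c(0, 0, 0), c(1, 0, 0)), 3, 2)
  ail <- atomic_interaction_line(list(p1, p2), 3)
  expect_setequal(ail$nacps, c(1L, 2L))
  expect_error(atomic_interaction_line(list(p1, p1), 3), "distinct")
  expect_error(atomic_interaction_line(list(p1), 3), "exactly 2")
  p3 <- gradient_path(pts(c(5, 0, 0), c(6, 0, 0)), 1, 2)
  expect_error(atomic_interaction_line(list(p1, p3), 3), "reference")
})

test_that("molecular-graph assembly pairs BCP-rooted paths and matches a brute-force oracle", {
  nacp <- function(p) critical_point(p, 3, -3)
  bcp <- function(p) critical_point(p, 3, -1, eigenvalues = c(-1, -0.5, 2),
                                    eigenvectors = diag(3))
  seg <- function(a, b, i, j) gradient_path(rbind(a, (a + b) / 2, b), i, j)
  cps <- list(nacp(c(-2, 0, 0)), nacp(c(0, 0, 0)), nacp(c(2, 0, 0)),
              bcp(c(-1, 0, 0)), bcp(c(1, 0, 0)))
  paths <- list(seg(c(-1, 0, 0), c(-2, 0, 0), 4, 1),
                seg(c(-1, 0, 0), c(0, 0, 0), 4, 2),
                seg(c(1, 0, 0), c(0, 0, 0), 5, 2),
                seg(c(1, 0, 0), c(2, 0, 0), 5, 3),
                # distractors: truncated path, NACP-NACP path
                seg(c(1, 0, 0), c(9, 0, 0), 5, -1),
                seg(c(0, 0, 0), c(2, 0, 0), 2, 3))
  g <- assemble_molecular_graph(paths, cps)
  expect_length(g$ails, 2)
  expect_setequal(vapply(g$ails, function(a) a$bcp, integer(1)), c(4L, 5L))
  expect_length(assemble_molecular_graph(list(), cps)$ails, 0)
  # a BCP with three NACP-terminated paths is skipped with a warning
  expect_warning(
    g2 <- assemble_molecular_graph(c(paths[1:4],
                                     list(seg(c(-1, 0, 0), c(2, 0, 0), 4, 3))),
                                   cps),
    "skipped")
  expect_length(g2$ails, 1)

  # independent brute-force pairing oracle on the benzene bond-path set
  top <- fixture_graph_topology("benzene")
  all_paths <- unlist(lapply(top$gvf$molecular_graph$ails,
                             function(a) a$paths), recursive = FALSE)
  labs <- cp_labels(top$critical_points)
  n_pairs <- 0L
  for (i in seq_along(all_paths)) for (j in seq_len(i - 1)) {
    pi <- all_paths[[i]]; pj <- all_paths[[j]]
    ends <- function(p) c(p$cp_start, p$cp_end)
    shared <- intersect(ends(pi), ends(pj))
    shared <- shared[shared > 0 & labs[shared] == "BCP"]
    far <- c(setdiff(ends(pi), shared), setdiff(ends(pj), shared))
    if (length(shared) == 1 && length(far) == 2 && far[1] != far[2] &&
        all(far > 0) && all(labs[far] == "NACP")) {
      n_pairs <- n_pairs + 1L
    }
  }
  expect_identical(n_pairs, 12L)
  expect_length(top$gvf$molecular_graph$ails, 12)
})

test_that("ring cycles are simple closed cycles over their nuclear attractors", {
  for (fx in c("benzene", "hf_pentamer", "s8")) {
    top <- fixture_graph_topology(fx)
    for (r in top$gvf$rings) {
      ails <- top$gvf$molecular_graph$ails[r$ails]
      ends <- do.call(rbind, lapply(ails, function(a) a$nacps))
      deg <- table(as.vector(ends))
      expect_true(all(deg == 2), label = paste(fx, "ring is 2-regular"))
      # exhaustive closure check through an independent graph library
      g <- igraph::graph_from_edgelist(apply(ends, 2, as.character),
                                       directed = FALSE)
      expect_equal(igraph::components(g)$no, 1)
      expect_equal(igraph::gsize(g), igraph::vcount(g))
      expect_identical(cp_labels(top$critical_points)[r$rcp], "RCP")
    }
  }
  expect_length(fixture_graph_topology("benzene")$gvf$rings, 1)
  expect_length(fixture_graph_topology("benzene")$gvf$rings[[1]]$ails, 6)
  expect_length(fixture_graph_topology("hf_pentamer")$gvf$rings[[1]]$ails, 10)
  # wide rings sit below the generic path-truncation density, which is
  # why ring tracing lowers its floor (S8's ring point is ~1e-5 au)
  s8 <- fixture_graph_topology("s8")
  s8_rcp <- which(cp_labels(s8$critical_points) == "RCP")
  expect_lt(s8$critical_points[[s8_rcp]]$scalars[["rho"]], 1e-4)
  # acyclic molecule: no rings, no cages
  hcn <- fixture_graph_topology("hcn")
  expect_length(hcn$gvf$rings, 0)
  expect_length(hcn$gvf$cages, 0)
})

test_that("every accepted critical point satisfies the signature constraints", {
  for (fx in c("h2", "hcn", "benzene", "s8")) {
    for (cp in fixture_cps(fx)) {
      expect_lte(abs(cp$signature), cp$rank)
      expect_identical((cp$signature - cp$rank) %% 2L, 0L)
      if (!is.null(cp$eigenvalues)) {
        cls <- classify_critical_point(cp$eigenvalues)
        expect_identical(cls$rank, cp$rank)
        expect_identical(cls$signature, cp$signature)
      }
    }
  }
})

test_that("classification agrees between analytic and finite-difference Hessians at located CPs", {
  for (fx in c("h2", "hcn", "benzene")) {
    den <- fixture_density(fx)
    for (cp in fixture_cps(fx)) {
      if (is.null(cp$eigenvalues)) next  # cusp attractors carry no Hessian
      hfd <- fd_hessian(den, cp$position, h = 1e-4)
      cls <- classify_critical_point(
        sort(eigen(hfd, symmetric = TRUE, only.values = TRUE)$values))
      expect_identical(cls$label, cp$label)
    }
  }
})
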