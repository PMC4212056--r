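test_that("universe sizes are exact powers of two", {
  expect_equal(universe_size(universe_spec(3, 1)), 8)
  expect_equal(universe_size(universe_spec(4, 1, directed = TRUE)), 4096)
  expect_identical(universe_size(universe_spec(6, 4)), 2^60)
})

test_that("cell weights follow the documented significance layout", {
  expect_equal(unname(cell_weights(universe_spec(4, 1))),
               c(1, 2, 4, 8, 16, 32))
  expect_equal(unname(cell_weights(universe_spec(3, 1, directed = TRUE))),
               c(1, 4, 16))
  expect_equal(unname(cell_weights(universe_spec(3, 2))), c(1, 4, 16))
  # shifted layout puts the s-t cell at highest significance
  expect_equal(unname(cell_weights(universe_spec(4, 1, shift_st = TRUE))),
               c(32, 1, 2, 4, 8, 16))
})

test_that("addresses encode and decode round-trip", {
  spec <- universe_spec(4, 1)
  expect_equal(subgraph_address(rep(0, 6), spec), 0)
  expect_equal(subgraph_address(c(0, 1, 0, 0, 0, 0), spec), 2)
  expect_error(subgraph_address(c(2, 0, 0, 0, 0, 0), spec), "out of range")
  d <- universe_spec(4, 1, directed = TRUE)
  # single forward edges everywhere except the s-t cell
  expect_equal(subgraph_address(c(0, 1, 1, 1, 1, 1), d), 1364)
  for (addr in c(0, 1, 77, 1364, 4095))
    expect_equal(subgraph_address(decode_address(addr, d), d), addr)
})

test_that("free-vertex permutation relabels cells and flips directed blocks", {
  spec <- universe_spec(4, 1)
  expect_equal(permuted_address(2, c(3, 4), spec), 2)   # identity
  expect_equal(permuted_address(2, c(4, 3), spec), 4)   # e13 <-> e14
  d <- universe_spec(4, 1, directed = TRUE)
  expect_equal(permuted_address(1364, c(4, 3), d), 2388)
  expect_equal(permuted_address(2388, c(4, 3), d), 1364)
})

test_that("canonical addresses are minimal, idempotent and orbit-constant", {
  expect_equal(canonical_address(0, universe_spec(4, 1)), 0)
  expect_equal(canonical_address(4, universe_spec(4, 1)), 2)
  d <- universe_spec(4, 1, directed = TRUE)
  expect_equal(canonical_address(2388, d), 1364)

  specs <- list(universe_spec(4, 1), d, universe_spec(4, 2),
                universe_spec(5, 1))
  for (spec in specs) {
    perms <- lapply(if (spec$n == 4) list(c(3, 4), c(4, 3)) else
                      list(c(3, 4, 5), c(5, 4, 3), c(4, 5, 3)), identity)
    set.seed(2024)
    x <- floor(runif(500) * universe_size(spec))
    cx <- canonical_address(x, spec)
    expect_equal(canonical_address(cx, spec), cx)
    for (p in perms)
      expect_equal(canonical_address(permuted_address(x, p, spec), spec), cx)
  }
})

test_that("static mapping reproduces the published worked addresses", {
  m411 <- build_static_mapping(universe_spec(4, 1, directed = TRUE))
  expect_equal(element_count(m411), 2112)
  expect_equal(element_of(1364, m411), element_of(2388, m411))
  expect_equal(element_of(1364, m411), 884)

  m420 <- build_static_mapping(universe_spec(4, 2))
  expect_equal(element_count(m420), 2176)
  expect_equal(element_of(1364, m420), 792)
  expect_equal(element_of(2388, m420), 1336)

  m410 <- build_static_mapping(universe_spec(4, 1))
  expect_equal(element_count(m410), 40)
  expect_equal(element_of(2, m410), element_of(4, m410))
  expect_equal(element_of(2, m410), 2)
  # exactly 20 elements carry the free-free edge bit (weight 32)
  ff <- sum(m410$elements %/% 32 %% 2 == 1)
  expect_equal(ff, 20)
})

test_that("static indices are contiguous in increasing canonical order", {
  m <- build_static_mapping(universe_spec(4, 2))
  expect_equal(sort(unique(m$index)), 0:(element_count(m) - 1))
  expect_equal(m$elements, sort(m$elements))
  # element 0 is the empty subgraph
  expect_equal(element_of(0, m), 0)
})

test_that("orbit sizes partition the universe", {
  for (spec in list(universe_spec(4, 1), universe_spec(4, 1, directed = TRUE),
                    universe_spec(5, 1))) {
    m <- build_static_mapping(spec)
    expect_equal(sum(table(m$index)), universe_size(spec))
    expect_equal(length(unique(m$index)), element_count(m))
  }
})

test_that("enumeration cap triggers an explicit refusal", {
  expect_error(build_static_mapping(universe_spec(4, 3), cap = 2^16),
               "dynamic")
  expect_error(vcp_cardinality(universe_spec(8, 2)), "refused")
})

test_that("dynamic ids induce the same partition as static indices", {
  for (spec in list(universe_spec(4, 1, directed = TRUE),
                    universe_spec(4, 2))) {
    stat <- build_static_mapping(spec)
    dyn <- dynamic_mapping(spec)
    set.seed(99)
    x <- unique(floor(runif(300) * universe_size(spec)))
    ds <- element_of(x, dyn)
    ss <- element_of(x, stat)
    # same partition: dynamic ids agree exactly when static ids agree
    expect_equal(outer(ds, ds, "=="), outer(ss, ss, "=="))
    # dynamic ids are canonical addresses
    expect_equal(ds, canonical_address(x, spec))
  }
})

test_that("dynamic memo stores at most the orbit of each query", {
  spec <- universe_spec(4, 2)
  dyn <- dynamic_mapping(spec)
  element_of(c(1364, 2388, 7), dyn)
  expect_lte(length(ls(dyn$memo)), 3 * 2)   # (n-2)! = 2 per query
  # two members of one orbit share an id
  expect_equal(element_of(1364, dyn) == element_of(2388, dyn),
               canonical_address(1364, spec) == canonical_address(2388, spec))
})

test_that("cell-vector dynamic ids work beyond 52 address bits", {
  spec <- universe_spec(4, 10)   # 60 address bits
  dyn <- dynamic_mapping(spec)
  cells <- c(0, 5, 0, 9, 0, 0)
  swapped <- c(0, 0, 5, 0, 9, 0)   # v3 <-> v4 image
  k1 <- dynamic_element(cells, dyn)
  k2 <- dynamic_element(swapped, dyn)
  expect_identical(as.character(k1), as.character(k2))
})

test_that("enumerated cardinalities match the Burnside orbit count", {
  cases <- list(list(3, 1, FALSE, 8), list(3, 2, FALSE, 64),
                list(4, 1, FALSE, 40), list(4, 1, TRUE, 2112),
                list(4, 2, FALSE, 2176), list(5, 1, FALSE, 240))
  for (cs in cases) {
    spec <- universe_spec(cs[[1]], cs[[2]], directed = cs[[3]])
    expect_equal(vcp_cardinality_burnside(spec), cs[[4]])
    expect_equal(vcp_cardinality(spec), cs[[4]])
  }
  # directionality introduces extra equivalences relative to doubled relations
  expect_lt(vcp_cardinality_burnside(universe_spec(4, 1, directed = TRUE)),
            vcp_cardinality_burnside(universe_spec(4, 2)))
})

test_that("mapping tables reload losslessly", {
  m <- build_static_mapping(universe_spec(4, 1, directed = TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mapping(m, path)
  m2 <- read_mapping(path)
  expect_equal(m2$index, m$index)
  expect_equal(m2$elements, m$elements)
  expect_equal(m2$spec$n, 4L)
  expect_equal(m2$spec$d, 1L)
})
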