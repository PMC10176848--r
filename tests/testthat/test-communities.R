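test_that("two positive triangles partition into two communities", {
  net <- makeNet(list(list("g__A", "g__B", 0.8), list("g__B", "g__C", 0.7),
                      list("g__A", "g__C", 0.6), list("g__D", "g__E", 0.9),
                      list("g__E", "g__F", 0.8), list("g__D", "g__F", 0.7)))
  asg <- partitionCommunities(net)
  mb <- communityMembership(asg)
  expect_equal(sort(unique(mb)), c(1L, 2L))
  expect_length(unique(mb[c("g__A", "g__B", "g__C")]), 1)
  expect_length(unique(mb[c("g__D", "g__E", "g__F")]), 1)
  # labels are deterministic: equal sizes, tie broken by smallest member
  expect_equal(unname(mb[["g__A"]]), 1L)
})

test_that("isolated and sub-minSize taxa stay unassigned; principles hold", {
  net <- makeNet(list(list("g__A", "g__B", 0.8)),
                 nodes = c("g__A", "g__B", "g__C"))
  asg <- partitionCommunities(net)
  mb <- communityMembership(asg)
  expect_equal(unname(mb[c("g__A", "g__B")]), c(1L, 1L))
  expect_true(is.na(mb[["g__C"]]))
  expect_equal(nrow(asg@violations), 0)

  # negative inter-community edge is recorded, not a violation
  net2 <- makeNet(list(list("g__A", "g__B", 0.8), list("g__C", "g__D", 0.7),
                       list("g__B", "g__C", -0.6)))
  asg2 <- partitionCommunities(net2)
  expect_equal(length(unique(na.omit(communityMembership(asg2)))), 2)
  expect_equal(nrow(asg2@interCommunityNegative), 1)
  expect_equal(nrow(asg2@violations), 0)
})

test_that("partition equals a union-find oracle on random signed graphs", {
  for (s in 1:8) {
    set.seed(700 + s)
    n <- sample(6:12, 1)
    nodes <- sprintf("g__N%02d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.25
    ed <- pairs[keep, , drop = FALSE]
    rho <- runif(nrow(ed), -1, 1)
    net <- makeNet(Map(function(a, b, r) list(a, b, r),
                       ed[, 1], ed[, 2], rho), nodes = nodes)
    asg <- partitionCommunities(net, minSize = 2L)
    mb <- communityMembership(asg)

    pos <- networkEdges(net)
    pos <- pos[pos$sign > 0, , drop = FALSE]
    roots <- unionFindComponents(nodes, pos)
    sizes <- table(roots)
    for (r in names(sizes)) {
      members <- nodes[roots == r]
      if (sizes[[r]] >= 2) {
        expect_length(unique(mb[members]), 1)
        expect_false(anyNA(mb[members]))
      } else expect_true(is.na(mb[members]))
    }
    # principle 2: every assigned taxon has a positive within-community edge
    for (tx in names(mb)[!is.na(mb)]) {
      nb <- c(pos$taxon_b[pos$taxon_a == tx], pos$taxon_a[pos$taxon_b == tx])
      expect_true(any(mb[nb] == mb[tx], na.rm = TRUE))
    }
    # partitions agree as set partitions (label-invariant)
    expect_equal(adjustedRandIndex(mb[!is.na(mb)],
                                   roots[names(mb)[!is.na(mb)]]), 1)
  }
})

test_that("reference matching follows the maximal-overlap rule", {
  cores <- referenceCores()
  net <- makeNet(list(list("g__Sphingomonas", "g__Bradyrhizobium", 0.8),
                      list("g__Foo", "g__Bar", 0.9)))
  asg <- matchToReference(partitionCommunities(net), cores)
  cm <- asg@coreMatch
  withSph <- cm$reference[cm$community ==
    communityMembership(asg)[["g__Sphingomonas"]]]
  expect_equal(withSph, "community 1")
  expect_true(is.na(cm$reference[cm$community ==
    communityMembership(asg)[["g__Foo"]]]))

  # overlap 2 with community 2 beats overlap 1 with community 1
  net2 <- makeNet(list(list("g__Neisseria", "g__Prevotella", 0.8),
                       list("g__Prevotella", "g__Sphingomonas", 0.7)))
  asg2 <- matchToReference(partitionCommunities(net2), cores)
  expect_equal(asg2@coreMatch$reference, "community 2")
  expect_equal(asg2@coreMatch$overlap, 2L)
})

test_that("degree summaries equal brute-force incidence counts", {
  tri <- makeNet(list(list("g__A", "g__B", 0.8), list("g__B", "g__C", 0.7),
                      list("g__A", "g__C", 0.6)))
  ds <- degreeSummary(tri, partitionCommunities(tri))
  expect_equal(unname(communityDegrees(ds, 1)), c(2L, 2L, 2L))
  expect_equal(degreeTable(ds)$mean_degree, 2)

  star <- makeNet(list(list("g__Hub", "g__L1", 0.8), list("g__Hub", "g__L2", 0.8),
                       list("g__Hub", "g__L3", 0.8), list("g__Hub", "g__L4", 0.8)))
  dsS <- degreeSummary(star, partitionCommunities(star))
  d <- communityDegrees(dsS, 1)
  expect_equal(unname(d[order(names(d))]),
               c(4L, 1L, 1L, 1L, 1L)[order(c("g__Hub", "g__L1", "g__L2",
                                             "g__L3", "g__L4"))])
  expect_equal(degreeTable(dsS)$mean_degree, 1.6)

  # random graph: degrees equal incidence counts; negative edges included
  set.seed(801)
  nodes <- sprintf("g__N%d", 1:9)
  pairs <- t(combn(nodes, 2))
  ed <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
  rho <- runif(nrow(ed), -1, 1)
  net <- makeNet(Map(function(a, b, r) list(a, b, r), ed[, 1], ed[, 2], rho),
                 nodes = nodes)
  asg <- partitionCommunities(net)
  dsR <- degreeSummary(net, asg)
  allEdges <- networkEdges(net)
  for (cmty in degreeTable(dsR)$community) {
    dg <- communityDegrees(dsR, cmty)
    for (tx in names(dg))
      expect_equal(unname(dg[tx]),
                   sum(allEdges$taxon_a == tx) + sum(allEdges$taxon_b == tx))
  }
})

test_that("degree comparison is a pooled two-sample t-test", {
  cores <- list(`community 1` = c("g__A", "g__D"))
  netA <- makeNet(list(list("g__A", "g__B", 0.8), list("g__B", "g__C", 0.7),
                       list("g__A", "g__C", 0.6)))
  asgA <- matchToReference(partitionCommunities(netA),
                           list(`community 1` = c("g__A")))
  res <- compareDegree(netA, netA, asgA, asgA, "community 1")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # closed-form oracle on raw degree lists via stats::t.test
  d1 <- c(2, 3, 4, 2, 5); d2 <- c(6, 7, 5, 8)
  ours <- pooledT(d1, d2)
  ref <- t.test(d1, d2, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  expect_equal(ours$df, unname(ref$parameter))

  # clear separation
  sep <- pooledT(c(2, 2, 2.1), c(5, 5, 5.1))
  expect_lt(sep$p, 0.01)

  # unmatched community errors
  expect_error(compareDegree(netA, netA, asgA, asgA, "community 9"),
               "not matched")
})
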