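test_that("simple Dollo placements are forced by minimality", {
  tree <- read_newick(text = five_tip_newick)

  all_present <- character_matrix(matrix(1L, 5, 3, dimnames = list(
    c("Out", "Mono", "Bdel", "Seis", "Acan"), paste0("c", 1:3))))
  tab <- dollo_events(all_present, tree)
  expect_true(all(tab$losses == 0L) && all(tab$gains == 0L))
  for (tip in tree_tips(tree)) expect_identical(cumulative_tip_losses(tab, tip), 0L)

  # absent only in the two Pararotatoria tips -> one loss on their stem
  m <- matrix(1L, 5, 1, dimnames = list(c("Out", "Mono", "Bdel", "Seis", "Acan"), "c1"))
  m[c("Seis", "Acan"), 1] <- 0L
  tab <- dollo_events(character_matrix(m), tree)
  expect_identical(tab$losses[tab$branch == "Pararotatoria"], 1L)
  expect_identical(sum(tab$losses), 1L)

  # single-tip absence -> one event on that terminal branch
  m[, 1] <- 1L; m["Mono", 1] <- 0L
  tab <- dollo_events(character_matrix(m), tree)
  expect_identical(tab$losses[tab$branch == "Mono"], 1L)
  expect_identical(sum(tab$losses), 1L)
})

test_that("Dollo loss counts equal the exhaustive minimum on random matrices", {
  set.seed(402)
  n_cases <- 0L
  for (rep in 1:60) {
    n_tips <- sample(3:6, 1)
    tree <- random_tree(n_tips)
    n_char <- sample(3:8, 1)
    vals <- sample(c(0L, 1L), n_tips * n_char, replace = TRUE, prob = c(0.4, 0.6))
    mat <- matrix(vals, n_tips, n_char,
                  dimnames = list(tree_tips(tree), paste0("c", seq_len(n_char))))
    tab <- dollo_events(character_matrix(mat), tree)
    for (j in seq_len(n_char)) {
      per_char <- vapply(attr(tab, "loss_events"), function(e) sum(e == paste0("c", j)),
                         integer(1))
      expect_identical(sum(per_char),
                       oracle_min_losses(tree, setNames(mat[, j], rownames(mat))),
                       info = sprintf("rep %d char %d", rep, j))
      n_cases <- n_cases + 1L
    }
  }
  expect_gte(n_cases, 300L)
})

test_that("with unknown cells the conservative count never beats the free minimum", {
  # unknowns neither rescue presence nor generate events, so the event count
  # is bounded below by the minimum in which unknown tips take any state
  set.seed(403)
  for (rep in 1:20) {
    n_tips <- sample(4:6, 1)
    tree <- random_tree(n_tips)
    vals <- sample(c(0L, 1L, NA), n_tips * 4, replace = TRUE, prob = c(0.3, 0.5, 0.2))
    mat <- matrix(vals, n_tips, 4,
                  dimnames = list(tree_tips(tree), paste0("c", 1:4)))
    tab <- dollo_events(character_matrix(mat), tree)
    for (j in 1:4) {
      per_char <- sum(vapply(attr(tab, "loss_events"),
                             function(e) sum(e == paste0("c", j)), integer(1)))
      expect_gte(per_char, oracle_min_losses(tree, setNames(mat[, j], rownames(mat))))
    }
  }
})

test_that("ancestrally absent characters gain once at the MRCA with Dollo losses below", {
  tree <- read_newick(text = five_tip_newick)
  m <- matrix(0L, 5, 2, dimnames = list(c("Out", "Mono", "Bdel", "Seis", "Acan"),
                                        c("g1", "g2")))
  m[c("Bdel", "Seis"), "g1"] <- 1L       # MRCA = Hemirotifera, loss in Acan below
  m["Mono", "g2"] <- 1L                  # single possessing tip
  pol <- polarity_spec(default = "absent")
  tab <- dollo_events(character_matrix(m), tree, pol)
  expect_identical(tab$gains[tab$branch == "Hemirotifera"], 1L)
  expect_identical(tab$losses[tab$branch == "Acan"], 1L)
  expect_identical(tab$gains[tab$branch == "Mono"], 1L)
  expect_identical(sum(tab$gains), 2L)

  # zero possessing tips -> warning, no events
  m0 <- matrix(0L, 5, 1, dimnames = list(rownames(m), "g0"))
  expect_warning(tab0 <- dollo_events(character_matrix(m0), tree, pol),
                 "zero possessing tips")
  expect_identical(sum(tab0$losses) + sum(tab0$gains), 0L)
})

test_that("outgroup polarity resolves ancestral states and excludes ties", {
  tree <- read_newick(text = "((Og1,Og2)Outs,(A,(B,C)BC)In)Root;")
  m <- matrix(1L, 5, 3, dimnames = list(c("Og1", "Og2", "A", "B", "C"),
                                        c("agree1", "agree0", "tie")))
  m[c("B", "C"), "agree1"] <- 0L                     # outgroups present -> losses count
  m[, "agree0"] <- 0L; m["A", "agree0"] <- 1L        # outgroups absent -> gain at A
  m["Og1", "tie"] <- 1L; m["Og2", "tie"] <- 0L       # outgroups disagree -> excluded
  pol <- polarity_spec(default = "outgroup", outgroups = c("Og1", "Og2"))
  states <- reconstruct_states(character_matrix(m), tree, pol)
  expect_identical(unname(states$ancestral), c("present", "absent", "excluded"))
  expect_identical(states$excluded, "tie")
  tab <- count_branch_events(states)
  expect_identical(tab$losses[tab$branch == "BC"], 1L)
  expect_identical(tab$gains[tab$branch == "A"], 1L)
})

test_that("unknown tip cells neither create events nor rescue presence", {
  tree <- read_newick(text = "((A,B)AB,(C,D)CD)Root;")
  m <- matrix(c(0L, NA, 1L, 1L), 4, 1, dimnames = list(c("A", "B", "C", "D"), "c1"))
  tab <- dollo_events(character_matrix(m), tree)
  # B unknown: AB has no definitely present tip -> single loss on the AB stem
  expect_identical(tab$losses[tab$branch == "AB"], 1L)
  expect_identical(sum(tab$losses), 1L)
})

test_that("cumulative tip losses are additive and monotone under added absences", {
  tree <- read_newick(text = five_tip_newick)
  set.seed(11)
  for (rep in 1:20) {
    m <- matrix(sample(c(0L, 1L), 5 * 6, replace = TRUE, prob = c(0.3, 0.7)), 5, 6,
                dimnames = list(c("Out", "Mono", "Bdel", "Seis", "Acan"), paste0("c", 1:6)))
    tab <- dollo_events(character_matrix(m), tree)
    for (tip in rownames(m)) {
      # additivity: path losses equal the tip's absent cells (no gains planted)
      expect_identical(cumulative_tip_losses(tab, tip), sum(m[tip, ] == 0L))
    }
    # monotonicity: adding an absence never decreases that tip's cumulative count
    tip <- sample(rownames(m), 1)
    present_cols <- which(m[tip, ] == 1L)
    if (length(present_cols)) {
      m2 <- m; m2[tip, present_cols[1]] <- 0L
      tab2 <- dollo_events(character_matrix(m2), tree)
      expect_gte(cumulative_tip_losses(tab2, tip), cumulative_tip_losses(tab, tip))
    }
  }
  expect_error(cumulative_tip_losses(dollo_events(tiny_matrix(),
                                                  read_newick(text = "((A,B),C);")), "Z"),
               "unknown tip")
})

test_that("shared_missing matches manual intersection and validates input", {
  m <- tiny_matrix()
  # by hand: c3 is absent in all three taxa; c4 absent in A and B only
  expect_identical(shared_missing(m, c("A", "B", "C")),
                   list(count = 1L, characters = "c3"))
  expect_identical(shared_missing(m, c("A", "B"))$characters, c("c3", "c4"))
  expect_identical(shared_missing(m, "C")$count, 2L)
  expect_error(shared_missing(m, character(0)), "nonempty")
  expect_error(shared_missing(m, "nope"), "not in matrix")

  all_present <- character_matrix(matrix(1L, 2, 3, dimnames = list(c("A", "B"), paste0("c", 1:3))))
  expect_identical(shared_missing(all_present, c("A", "B"))$count, 0L)
})
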