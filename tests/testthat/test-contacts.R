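test_that("the 3 A contact boundary is inclusive", {
  for (d in c(2.99, 3.00, 3.01)) {
    ct <- frame_contacts(pair_structure(d), "chain A", "chain B")
    expect_equal(nrow(ct), as.integer(d <= 3.00), info = paste("d =", d))
  }
})

test_that("cell-list and brute-force scans agree on random frames", {
  set.seed(23)
  for (rep in 1:30) {
    n <- 50
    atoms <- rbind(toy_atoms(n / 2, chain = "A"),
                   toy_atoms(n / 2, chain = "B"))
    atoms$serial <- seq_len(n)
    s <- structure3d(atoms, matrix(runif(3 * n, 0, 15), n))
    a <- frame_contacts(s, "chain A", "chain B", method = "brute")
    b <- frame_contacts(s, "chain A", "chain B", method = "cell")
    expect_equal(a[order(a$key_a, a$key_b), ],
                 b[order(b$key_a, b$key_b), ], ignore_attr = TRUE)
  }
})

test_that("persistence fractions and classes follow the 80/90 rule", {
  tr <- pair_trajectory(10, contact_frames = 1:9)
  tab <- contact_persistence(tr, "chain A", "chain B")
  expect_equal(tab$fraction, 0.9)
  expect_equal(tab$class, "very_persistent")

  tr8 <- pair_trajectory(10, contact_frames = 1:8)
  expect_equal(contact_persistence(tr8, "chain A", "chain B")$class,
               "persistent")
  tr_all <- pair_trajectory(6, contact_frames = 1:6)
  expect_equal(contact_persistence(tr_all, "chain A", "chain B")$fraction,
               1.0)
  tr_poor <- pair_trajectory(10, contact_frames = 1:7)
  expect_equal(contact_persistence(tr_poor, "chain A", "chain B")$class,
               "poor")
})

test_that("split-window persistence is the frame-weighted mean", {
  tr <- pair_trajectory(20, contact_frames = c(1:9, 12, 15:20))
  w1 <- 1:8; w2 <- 9:20
  f_all <- contact_persistence(tr, "chain A", "chain B")$fraction
  f1 <- contact_persistence(tr, "chain A", "chain B", window = w1)$fraction
  f2 <- contact_persistence(tr, "chain A", "chain B", window = w2)$fraction
  expect_equal(f_all,
               (length(w1) * f1 + length(w2) * f2) / (length(w1) + length(w2)))
})

test_that("enlarging the cutoff never removes a contact pair", {
  set.seed(29)
  n <- 30
  atoms <- rbind(toy_atoms(n / 2, chain = "A"),
                 toy_atoms(n / 2, chain = "B"))
  atoms$serial <- seq_len(n)
  s <- structure3d(atoms, matrix(runif(3 * n, 0, 12), n))
  prev <- character()
  for (cutoff in c(2, 3, 4, 6, 9)) {
    ct <- frame_contacts(s, "chain A", "chain B", cutoff = cutoff)
    keys <- paste(ct$key_a, ct$key_b)
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("residue profile keeps each residue's best partner fraction", {
  tab <- data.frame(
    key_a = c("C:771:ALA", "C:771:ALA", "C:772:ALA"),
    key_b = c("A:10:GLY", "A:20:GLY", "B:5:GLY"),
    n_contact_frames = c(19, 11, 17), n_window_frames = 20,
    fraction = c(0.95, 0.55, 0.85),
    class = c("very_persistent", "poor", "persistent"))
  prof <- residue_profile(tab)
  r771 <- prof[prof$resid == 771, ]
  expect_equal(r771$max_fraction, 0.95)
  expect_equal(r771$class, "very_persistent")
  expect_equal(r771$colour, "green")
  expect_equal(prof$colour[prof$resid == 772], "yellow")

  one <- residue_profile(tab[3, ])
  expect_equal(nrow(one), 1)
  expect_equal(one$max_fraction, 0.85)
})

test_that("class counts partition the contact table", {
  set.seed(31)
  gen <- make_contact_trajectory(runif(6), n_frames = 40, seed = 99)
  tab <- contact_persistence(gen$trajectory, "chain A", "chain B")
  expect_true(all(tab$fraction >= 0 & tab$fraction <= 1))
  expect_equal(sum(table(tab$class)), nrow(tab))
})

test_that("water bridges match a brute-force triple loop", {
  set.seed(37)
  n <- 6
  atoms <- rbind(toy_atoms(n, chain = "A"),
                 toy_atoms(n, chain = "B"),
                 toy_atoms(4, chain = "W", resname = "HOH", name = "O",
                           element = "O"))
  atoms$serial <- seq_len(nrow(atoms))
  cutoff <- 3.5
  frames <- lapply(1:20, function(f)
    matrix(runif(3 * nrow(atoms), 0, 10), nrow(atoms)))
  tr <- trajectory(structure3d(atoms, frames[[1]]), frames)
  got <- water_bridges(tr, "chain A", "chain B", "water", cutoff)

  # oracle: explicit loops over water / residue-A / residue-B
  counts <- new.env()
  iw <- 2 * n + 1:4
  for (f in 1:20) {
    xyz <- frames[[f]]
    seen <- character()
    for (w in iw) for (a in 1:n) for (b in n + 1:n) {
      da <- sqrt(sum((xyz[w, ] - xyz[a, ])^2))
      db <- sqrt(sum((xyz[w, ] - xyz[b, ])^2))
      if (da <= cutoff && db <= cutoff) {
        k <- paste0("A:", a, ":GLY|B:", b - n, ":GLY")
        if (!(k %in% seen)) {
          seen <- c(seen, k)
          assign(k, (if (exists(k, counts)) get(k, counts) else 0) + 1,
                 counts)
        }
      }
    }
  }
  expect_equal(nrow(got), length(ls(counts)))
  for (k in ls(counts))
    expect_equal(
      got$n_contact_frames[paste(got$key_a, got$key_b, sep = "|") == k],
      get(k, counts))
})

test_that("no waters gives an empty table; empty windows are errors", {
  tr <- pair_trajectory(5, 1:5)
  expect_equal(nrow(water_bridges(tr, "chain A", "chain B", "water")), 0)
  expect_error(contact_persistence(tr, "chain A", "chain B",
                                   window = integer()), "window error")
  expect_error(frame_contacts(get_frame(tr, 1), "water", "chain B"),
               "selection error")
})
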