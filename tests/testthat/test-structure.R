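test_that("parser applies the altloc policy and rejects bad input", {
  # hand-built two-conformer glutamate: only altloc A must survive
  lines <- c(
    "ATOM      1  CA  GLU A   1      11.000  10.000  10.000  1.00  0.00           C",
    "ATOM      2  CD AGLU A   1      12.000  10.000  10.000  0.50  0.00           C",
    "ATOM      3  CD BGLU A   1      12.500  10.000  10.000  0.50  0.00           C",
    "ATOM      4  OE1AGLU A   1      13.000  10.000  10.000  0.50  0.00           O",
    "ATOM      5  OE1BGLU A   1      13.500  10.000  10.000  0.50  0.00           O",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb", lines = lines)
  st <- parse_structure(path)
  expect_equal(nrow(st$atoms), 3)             # CA + altloc-A CD/OE1
  expect_equal(st$atoms$x[st$atoms$elety == "OE1"], 13.0)

  empty <- withr::local_tempfile(fileext = ".pdb", lines = "END")
  expect_error(parse_structure(empty))
  expect_error(parse_structure("/nonexistent/file.pdb"), "not found")
})

test_that("planted contacts are found at their construction distances", {
  pairs <- data.frame(negative = c("GLU", "ASP", "GLU"),
                      positive = c("LYS", "ARG", "LYS"),
                      distance = c(3.0, 3.5, 3.9))
  st <- parse_structure(gen_toy_complex(pairs, decoys = 6, seed = 2))
  ct <- find_ionic_contacts(st, "A", "B", cutoff = 4.0)
  expect_equal(nrow(ct), 3)
  expect_equal(ct$distance, c(3.0, 3.5, 3.9), tolerance = 1e-3)
  # dedup keeps the single closest atom pair per residue pair
  expect_false(any(duplicated(paste(ct$neg_key, ct$pos_key))))

  # above-cutoff pair and decoy-only constructions yield nothing
  far <- parse_structure(gen_toy_complex(
    data.frame(negative = "GLU", positive = "LYS", distance = 4.5),
    decoys = 0, seed = 1))
  expect_equal(nrow(find_ionic_contacts(far, "A", "B", 4.0)), 0)
  deco <- parse_structure(gen_toy_complex(pairs[0, ], decoys = 10, seed = 3))
  expect_equal(nrow(find_ionic_contacts(deco, "A", "B", 4.0)), 0)
  expect_equal(nrow(find_ionic_contacts(st, "A", "B", 0)), 0)
  expect_error(find_ionic_contacts(st, c("A", "B"), "B"), "overlap")
})

test_that("contact detection matches the all-pairs oracle and is symmetric", {
  set.seed(31)
  pairs <- data.frame(
    negative = sample(c("GLU", "ASP"), 5, replace = TRUE),
    positive = sample(c("LYS", "ARG"), 5, replace = TRUE),
    distance = round(runif(5, 2.5, 5.5), 2))
  st <- parse_structure(gen_toy_complex(pairs, decoys = 8, seed = 5))
  for (cutoff in c(3.0, 4.0, 5.0)) {
    got <- find_ionic_contacts(st, "A", "B", cutoff)
    want <- oracle_contacts(st, "A", "B", cutoff)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$distance, want$distance, tolerance = 1e-12)
      expect_setequal(paste(got$neg_key, got$pos_key),
                      paste(want$neg_key, want$pos_key))
    }
  }
  # swapping the groups re-assigns roles but returns the same contacts
  a <- find_ionic_contacts(st, "A", "B", 4.0)
  b <- find_ionic_contacts(st, "B", "A", 4.0)
  expect_equal(a$distance, b$distance)
  expect_setequal(paste(a$neg_key, a$pos_key), paste(b$neg_key, b$pos_key))
})

test_that("contact count is monotone non-decreasing in the cutoff", {
  pairs <- data.frame(negative = rep("GLU", 4), positive = rep("LYS", 4),
                      distance = c(2.8, 3.4, 4.2, 5.1))
  st <- parse_structure(gen_toy_complex(pairs, decoys = 4, seed = 9))
  counts <- vapply(seq(2, 6, by = 0.5), function(cf)
    nrow(find_ionic_contacts(st, "A", "B", cf)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("groove grouping assigns every contact exactly once", {
  pairs <- data.frame(negative = c("GLU", "ASP", "GLU"),
                      positive = c("LYS", "ARG", "LYS"),
                      distance = c(3.0, 3.5, 3.9))
  st <- parse_structure(gen_toy_complex(pairs, decoys = 0, seed = 2))
  ct <- find_ionic_contacts(st, "A", "B", 4.0)
  im <- interface_map(ct, c(A = "alpha4", B = "Rpt6"))
  expect_equal(sum(im$counts), length(unique(ct$neg_key)))
  expect_equal(nrow(im$contacts), nrow(ct))
  expect_false(any(duplicated(unlist(im$groups))))
  expect_error(interface_map(ct, c(A = "alpha4")), "no subunit annotation")
})

test_that("alignment maps positions, shifts across insertions and flags charge loss", {
  m <- align_and_map("ACDEFGHIK", "ACDEFGHIK")
  expect_true(all(m$template_pos == m$target_pos))
  expect_true(all(m$identical))

  # one insertion in the target shifts all downstream positions by +1
  m2 <- align_and_map("ACDEFGHIKLMNPQRSTVWY", "ACDEFGGHIKLMNPQRSTVWY")
  aligned <- m2[!is.na(m2$template_pos) & !is.na(m2$target_pos), ]
  expect_true(all(aligned$target_pos[aligned$template_pos <= 6] ==
                    aligned$template_pos[aligned$template_pos <= 6]))
  expect_true(all(aligned$target_pos[aligned$template_pos >= 7] ==
                    aligned$template_pos[aligned$template_pos >= 7] + 1))
  # mapping is injective and order-preserving
  expect_false(any(duplicated(stats::na.omit(m2$target_pos))))
  expect_true(!is.unsorted(stats::na.omit(m2$target_pos)))

  # charged template residue aligned to uncharged target: kept but flagged
  m3 <- align_and_map("AAEAA", "AAQAA")
  row <- m3[m3$template_pos == 3, ]
  expect_equal(row$target_aa, "Q")
  expect_false(row$charge_conserved)
  expect_error(align_and_map("ACDX", "ACDE"), "illegal")
  expect_error(align_and_map("", "ACDE"), "empty")
})

test_that("contact transfer re-indexes, drops lost charges and counts them", {
  pairs <- data.frame(negative = c("GLU", "ASP"), positive = c("LYS", "LYS"),
                      distance = c(3.0, 3.5))
  st <- parse_structure(gen_toy_complex(pairs, decoys = 0, seed = 1))
  ct <- find_ionic_contacts(st, "A", "B", 4.0)

  identity_map <- function(aa) data.frame(
    template_pos = seq_along(aa), target_pos = seq_along(aa),
    template_aa = aa, target_aa = aa,
    identical = TRUE, charge_conserved = TRUE)
  tr <- transfer_contacts(ct, list(A = identity_map(c("E", "D")),
                                   B = identity_map(c("K", "K"))))
  expect_equal(tr$contacts$neg_key, ct$neg_key)
  expect_equal(tr$dropped_negative + tr$dropped_positive, 0L)

  # E at template position 1 aligned to Q: dropped and reported
  mapA <- data.frame(template_pos = 1:2, target_pos = 1:2,
                     template_aa = c("E", "D"), target_aa = c("Q", "D"),
                     identical = c(FALSE, TRUE),
                     charge_conserved = c(FALSE, TRUE))
  tr2 <- transfer_contacts(ct, list(A = mapA,
                                    B = identity_map(c("K", "K"))))
  expect_equal(nrow(tr2$contacts), 1)
  expect_equal(tr2$dropped_negative, 1L)
  expect_error(transfer_contacts(ct, list(A = mapA)), "no residue mapping")
})
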