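make_spot_row <- function(intens) {
  # intens: rounds x channels matrix
  row <- data.frame(spot = 1L, x = 0, y = 0)
  for (r in seq_len(nrow(intens))) for (ch in seq_len(ncol(intens)))
    row[[sprintf("int_r%d_c%d", r, ch)]] <- intens[r, ch]
  row
}

test_that("base calling extracts the argmax channel with max/sum quality", {
  intens <- rbind(c(10, 0, 0, 0), c(0, 8, 2, 0), c(1, 1, 6, 2), c(0, 0, 0, 4))
  calls <- call_bases(make_spot_row(intens))
  expect_identical(calls$barcode, "ACGT")
  expect_equal(unname(unlist(calls[1, c("qs_r1", "qs_r2", "qs_r3", "qs_r4")])),
               c(1, 0.8, 0.6, 1))
  expect_equal(calls$min_qs, 0.6)
  expect_false(calls$tie)
})

test_that("uniform intensities tie-break to channel 1 and are flagged", {
  intens <- rbind(c(5, 5, 5, 5), c(9, 0, 0, 0), c(9, 0, 0, 0), c(9, 0, 0, 0))
  expect_message(calls <- call_bases(make_spot_row(intens)), "tie")
  expect_identical(substr(calls$barcode, 1, 1), "A")
  expect_equal(calls$qs_r1, 0.25)
  expect_true(calls$tie)
})

test_that("an all-zero round leaves quality undefined and spot rejected", {
  intens <- rbind(c(0, 0, 0, 0), c(9, 0, 0, 0), c(9, 0, 0, 0), c(9, 0, 0, 0))
  calls <- call_bases(make_spot_row(intens))
  expect_true(is.na(calls$min_qs))
  cb <- generate_codebook(4, seed = 1)
  dec <- decode_spots(calls, cb)
  expect_identical(dec$status, "low_quality")
})

test_that("decoding accepts codewords above threshold and rejects by reason", {
  cb <- generate_codebook(49, seed = 7)
  word <- unname(cb[1])
  letters4 <- strsplit(word, "")[[1]]
  mk_intens <- function(letters4, qs) {
    m <- matrix(0, 4, 4)
    for (r in 1:4) {
      ch <- match(letters4[r], c("A", "C", "G", "T"))
      m[r, ch] <- 10
      # spread the remainder over the other channels so max/sum = qs[r]
      # while the argmax stays on the true channel
      rest <- 10 / qs[r] - 10
      m[r, setdiff(1:4, ch)] <- rest / 3
    }
    m
  }
  good <- call_bases(make_spot_row(mk_intens(letters4, c(0.9, 0.8, 0.95, 0.7))))
  dec <- decode_spots(good, cb)
  expect_identical(dec$status, "ok")
  expect_identical(dec$gene, names(cb)[1])
  low <- call_bases(make_spot_row(mk_intens(letters4, c(0.9, 0.4, 0.95, 0.7))))
  expect_identical(decode_spots(low, cb)$status, "low_quality")
  expect_error(decode_spots(good, stats::setNames("ACG", "g1")), "length")
})

test_that("every single-base corruption of every codeword is rejected", {
  cb <- generate_codebook(49, seed = 7)
  alphabet <- c("A", "C", "G", "T")
  genes_hit <- 0L
  for (w in unname(cb)) {
    for (pos in 1:4) for (sub in setdiff(alphabet,
                                         substr(w, pos, pos))) {
      corrupt <- w
      substr(corrupt, pos, pos) <- sub
      calls <- data.frame(spot = 1L, x = 0, y = 0, barcode = corrupt,
                          qs_r1 = 1, qs_r2 = 1, qs_r3 = 1, qs_r4 = 1,
                          min_qs = 1, tie = FALSE)
      dec <- decode_spots(calls, cb)
      expect_identical(dec$status, "not_in_codebook")
      if (!is.na(dec$gene)) genes_hit <- genes_hit + 1L
    }
  }
  expect_identical(genes_hit, 0L)  # never silently remapped
})

test_that("spots are assigned to the nearest nucleus with id tie-break", {
  nuclei <- data.frame(cell = c(2L, 1L), x = c(0, 10), y = c(0, 0))
  dec <- data.frame(spot = 1:3, x = c(0, 5, 30), y = 0,
                    gene = "Th", status = "ok")
  asn <- assign_spots_to_cells(dec, nuclei, max_radius = 8)
  expect_identical(asn$assignments$cell, c(2L, 1L))  # equidistant -> lower id
  expect_identical(asn$n_unassigned, 1L)
  expect_equal(asn$counts["1", "Th"], 1L)
  expect_error(assign_spots_to_cells(dec, nuclei[0, ], 5), "empty")
})

test_that("noise-free layouts assign nearly all spots to the true cell", {
  cb <- generate_codebook(12, seed = 2)
  ins <- generate_insitu(cb, insitu_layout(n_cells = 64, spacing = 30,
                                           spots_per_cell = 10), seed = 3)
  dec <- decode_spots(call_bases(ins$spots), cb)
  asn <- assign_spots_to_cells(dec, ins$nuclei, max_radius = 15)
  merged <- merge(asn$assignments, ins$truth, by = "spot")
  expect_gte(mean(merged$cell.x == merged$cell.y), 0.99)
  expect_gte(nrow(merged) / nrow(ins$spots), 0.99)
})

test_that("decoding accuracy does not increase with noise", {
  cb <- generate_codebook(20, seed = 4)
  acc <- vapply(c(0, 15, 30, 45, 60), function(ns) {
    ins <- generate_insitu(cb, insitu_layout(n_cells = 50,
                                             spots_per_cell = 10),
                           noise_sd = ns, seed = 9)
    dec <- decode_spots(call_bases(ins$spots), cb)
    mean(!is.na(dec$gene) & dec$gene == ins$truth$gene)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0))
  expect_equal(acc[1], 1)
})

test_that("the four in situ filters match hand-computed survivors", {
  genes <- c("Th", "Pitx3", "eGFP", "Nxph4", "Gad2", "Slc6a3", "Vip")
  counts <- matrix(0L, 14, length(genes),
                   dimnames = list(sprintf("cell%02d", 1:14), genes))
  counts[1:12, "Th"] <- 5L          # cells 1-12 pass the gate
  counts[13, "Gad2"] <- 3L          # cell 13 fails rule 1 (no gate gene)
  counts[14, "Pitx3"] <- 1L         # cell 14 passes gate via Pitx3
  counts[1:12, "Gad2"] <- 2L        # Gad2 in 12 cells -> kept by rule 2
  counts[1:9, "Slc6a3"] <- 1L       # Slc6a3 in 9 cells -> removed by rule 2
                                    # (Pitx3, in 1 cell, also falls to rule 2)
  counts[1:11, "Vip"] <- 1L         # Vip in 11 cells -> kept
  counts[1:12, "Nxph4"] <- 4L       # removed by rule 3 regardless
  counts[1:12, "eGFP"] <- 2L        # removed by rule 3
  # after rules 2-3 the panel is {Th, Gad2, Vip}; cells 1-11 express all
  # three, cell 12 only Th+Gad2, cell 14 nothing -> rule 4 drops 12 and 14
  filt <- filter_insitu_cells(counts)
  expect_setequal(rownames(filt), sprintf("cell%02d", 1:11))
  expect_setequal(colnames(filt), c("Th", "Gad2", "Vip"))
  removed <- attr(filt, "removed")
  expect_equal(unname(removed), c(1, 2, 2, 2))
  # idempotence on this table
  twice <- filter_insitu_cells(filt)
  expect_equal(unclass(twice), unclass(filt), ignore_attr = TRUE)
  expect_error(filter_insitu_cells(counts[, "Gad2", drop = FALSE]),
               "gate")
})

test_that("lineage proportions roll up to the two Dat branches", {
  labels <- c(rep("T-Dathigh", 40), rep("AT-Dathigh", 30),
              rep("VT-Dathigh", 19), rep("G-Datlow", 6),
              rep("N-Datlow", 5), rep("none", 10))
  props <- quantify_lineage_proportions(labels)
  expect_equal(sum(props$lineage), 1)
  expect_equal(unname(props$branch["dat_high"]), 0.89)
  expect_equal(unname(props$branch["dat_low"]), 0.11)
  expect_identical(props$n, 100L)
  single <- quantify_lineage_proportions(rep("G-Datlow", 5))
  expect_equal(unname(single$lineage["G-Datlow"]), 1)
  expect_error(quantify_lineage_proportions(rep("none", 3)), "none")
})
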