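test_that("default montage is the 16-site 10-20 subset, in order", {
  m <- default_montage()
  expect_s3_class(m, "montage")
  expect_identical(as.character(m),
                   c("Fp1", "Fp2", "F3", "F4", "Fz", "F7", "F8", "C3",
                     "C4", "P3", "P4", "Pz", "T5", "T6", "O1", "O2"))
  expect_error(montage(c("a", "a")), "unique")
  expect_error(montage(c("a", " ")), "non-empty")
  expect_error(montage(character(0)), "at least one")
})

test_that("recording construction validates shape, finiteness and rate", {
  expect_error(eeg_recording(matrix(0, 3, 10)), "channels")
  expect_error(eeg_recording(matrix(NA_real_, 16, 10)), "finite")
  expect_error(eeg_recording(matrix(0, 16, 10), fs = 0), "fs")
  rec <- eeg_recording(matrix(0, 16, 10))
  expect_equal(rec$fs, 200)
  expect_equal(nrow(rec$data), 16)
})

test_that("channel reordering is a pure permutation", {
  set.seed(1)
  scrambled <- sample(as.character(default_montage()))
  rec <- eeg_recording(matrix(rnorm(16 * 50), 16, 50),
                       montage = montage(scrambled))
  out <- reorder_channels(rec, default_montage())
  expect_identical(as.character(out$montage),
                   as.character(default_montage()))
  for (ch in scrambled) {
    expect_identical(out$data[ch, ], unname(rec$data[which(scrambled == ch), ]))
  }
  # matching ignores case and padding (EDF label fields are padded)
  rec2 <- eeg_recording(matrix(rnorm(16 * 10), 16, 10),
                        montage = montage(toupper(paste0(" ", scrambled))))
  expect_silent(reorder_channels(rec2, default_montage()))
  # a missing channel is an error that names it
  rec3 <- eeg_recording(matrix(0, 15, 10),
                        montage = montage(setdiff(scrambled, "O2")))
  expect_error(reorder_channels(rec3), "O2")
})

test_that("labeled matrix TSV round-trips bit-exactly", {
  set.seed(2)
  m <- matrix(rnorm(16 * 16), 16, 16)
  m <- (m + t(m)) / 2
  f <- withr::local_tempfile(fileext = ".tsv")
  labs <- as.character(default_montage())
  write_matrix_tsv(m, labs, labs, f)
  back <- read_matrix_tsv(f)
  expect_identical(unname(back), unname(m))   # bit-exact
  expect_identical(rownames(back), labs)
  # rectangular case: header plus one line per row
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(matrix(1:6 / 7, 2, 3), c("r1", "r2"),
                   c("c1", "c2", "c3"), f2)
  expect_length(readLines(f2), 3)
  expect_error(write_matrix_tsv(matrix(0, 2, 2), c("a", "b", "c"),
                                c("x", "y"), f2), "row labels")
})

test_that("EDF files round-trip within 16-bit quantization and reorder", {
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(16 * 400) * 50, 16, 400),
                       subject_id = "edge01")
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f)
  expect_identical(as.character(back$montage), as.character(rec$montage))
  expect_equal(back$fs, 200)
  expect_equal(back$subject_id, "edge01")
  quantum <- 2 * pmax(ceiling(apply(abs(rec$data), 1, max)), 1) / 65535
  expect_lt(max(abs(back$data - rec$data) / quantum), 0.51)
  # scrambled channel order in the file is undone by read_recording
  scr <- sample(16)
  rec2 <- eeg_recording(rec$data[scr, ], montage = montage(
    as.character(rec$montage)[scr]), subject_id = "edge02")
  f2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec2, f2)
  out <- read_recording(f2, default_montage())
  expect_identical(as.character(out$montage),
                   as.character(default_montage()))
  expect_lt(max(abs(out$data - rec$data)), 0.01)
})

test_that("an independent EDF reader (python-mne) agrees with ours", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(16 * 200) * 30, 16, 200),
                       subject_id = "xcheck")
  f <- withr::local_tempfile(fileext = ".edf")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_edf(rec, f)
  code <- paste0(
    "import mne, numpy; ",
    "raw = mne.io.read_raw_edf('", f, "', verbose='ERROR'); ",
    "numpy.savetxt('", csv, "', raw.get_data() * 1e6, delimiter=',')")
  status <- system2("python", c("-c", shQuote(code)),
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  mne_data <- as.matrix(read.csv(csv, header = FALSE))
  ours <- read_edf(f)$data
  expect_lt(max(abs(mne_data - ours)), 1e-6)
})

test_that("text recordings carry fs and reorder like EDF", {
  rec <- eeg_recording(matrix(rnorm(16 * 60), 16, 60), subject_id = "t1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_recording_tsv(rec, f)
  back <- read_recording(f, default_montage())
  expect_equal(back$data, rec$data, tolerance = 0)
  expect_equal(back$fs, 200)
  expect_error(read_recording(f, fs = 250), "mismatch")
  expect_error(read_recording("no/such/file.tsv"), "no such file")
})

test_that("metadata tables are validated and round-trip", {
  df <- data.frame(subject_id = c("a", "b"), group = c("control", "patient"),
                   session = c("none", "pre"), bprs = c(NA, 50),
                   age = c(30, 40))
  f <- withr::local_tempfile(fileext = ".csv")
  write_subject_meta(df, f)
  back <- read_subject_meta(f)
  expect_equal(as.character(back$group), c("control", "patient"))
  expect_equal(back$bprs, c(NA, 50))
  expect_error(subject_meta(data.frame(subject_id = "a", group = "dog")),
               "group")
  expect_error(subject_meta(transform(df, bprs = c(-1, 2))), "nonnegative")
  expect_error(subject_meta(df[c(1, 1), ]), "duplicate")
})
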