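test_that("an empty collection round-trips as a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_checkins(empty <- checkin_records(character(), character(),
                                          numeric()), path, "csv")
  expect_identical(readLines(path)[1],
                   "visitor_id,venue_id,check_in_time,check_out_time,reason,liability")
  expect_equal(nrow(read_checkins(path, "csv")), 0L)
})

test_that("records round-trip field-for-field through csv and jsonl", {
  rec <- make_records(25, open_fraction = 0.2)
  for (fmt in c("csv", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_checkins(rec, path, fmt)
    back <- read_checkins(path, fmt)
    rownames(rec) <- rownames(back) <- NULL
    expect_equal(back, rec, info = fmt)
  }
})

test_that("writing is byte-stable under the fixed field order", {
  rec <- make_records(100, seed = 7)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_checkins(rec, p1, "csv")
  write_checkins(read_checkins(p1, "csv"), p2, "csv")
  expect_identical(readLines(p1), readLines(p2))
})

test_that("malformed rows are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"visitor_id":"v1","venue_id":"a","check_in_time":"2020-05-01T09:00:00Z","check_out_time":"2020-05-01T10:00:00Z"}',
    '{"visitor_id":"v2","venue_id":"a","check_in_time":"2020-05-01T11:00:00Z","check_out_time":"2020-05-01T10:30:00Z"}'
  ), path)
  expect_error(read_checkins(path, "jsonl"), "line 2")

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("visitor_id,venue_id,check_in_time,check_out_time,reason,liability",
               "v1,a,not-a-time,,,"), csv)
  expect_error(read_checkins(csv, "csv"), "check_in_time.*line 2")
  expect_error(read_checkins(withr::local_tempfile(fileext = ".csv"), "csv"),
               "not found")
})

test_that("occupancy counts half-open sessions", {
  rec <- checkin_records("v1", "lib-01",
                         "2020-05-01T09:00:00Z", "2020-05-01T10:00:00Z")
  expect_equal(occupancy(rec, "lib-01", "2020-05-01T09:00:00Z"), 1L)
  expect_equal(occupancy(rec, "lib-01", "2020-05-01T09:59:59Z"), 1L)
  expect_equal(occupancy(rec, "lib-01", "2020-05-01T10:00:00Z"), 0L)
  expect_equal(occupancy(rec, "lib-01", "2020-05-01T08:59:59Z"), 0L)
  expect_equal(occupancy(rec[0, ], "lib-01", "2020-05-01T09:30:00Z"), 0L)
  expect_equal(occupancy(rec, "nowhere", "2020-05-01T09:30:00Z"), 0L)
})

test_that("occupancy matches a brute-force interval scan on random sessions", {
  rec <- make_records(50, venues = "hall", seed = 11, open_fraction = 0.1)
  ts <- seq(min(rec$t_in) - 100, max(rec$t_out, na.rm = TRUE) + 100,
            length.out = 40)
  brute <- vapply(ts, function(t) {
    hits <- 0L
    for (i in seq_len(nrow(rec))) {
      if (rec$t_in[i] <= t && (is.na(rec$t_out[i]) || rec$t_out[i] > t))
        hits <- hits + 1L
    }
    hits
  }, integer(1))
  expect_equal(occupancy(rec, "hall", ts), brute)
  expect_true(all(brute >= 0))
})

test_that("qr payloads round-trip, including reserved characters", {
  expect_identical(encode_qr_payload("lib-01"), "healthpass://venue/lib-01")
  expect_identical(decode_qr_payload("healthpass://venue/lib-01"), "lib-01")
  set.seed(3)
  pool <- c(letters, LETTERS, 0:9, "/", "?", "#", " ", "%", "&", "=", "+")
  for (i in 1:25) {
    id <- paste(sample(pool, sample(1:12, 1), replace = TRUE), collapse = "")
    expect_identical(decode_qr_payload(encode_qr_payload(id)), id)
  }
  expect_error(encode_qr_payload(""), "non-empty")
  expect_error(decode_qr_payload("https://venue/lib-01"), "payload")
})
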