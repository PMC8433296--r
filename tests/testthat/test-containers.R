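test_that("data records lay out at the fixed offsets, big-endian", {
  # OF record, FID 1, two payload bytes: 12 bytes built by hand
  r <- data_record(1, "OF", data = charToRaw("hi"))
  b <- serialize_data_record(r)
  expect_identical(b, as.raw(c(0x00, 0, 0, 0, 1, 0x00, 0, 0, 0, 2, 0x68, 0x69)))
  # header-only CPF record is exactly 10 bytes
  expect_length(serialize_data_record(data_record(2, "CPF")), 10)
  # SPF: offset-6 field holds the tool FID, no tool bytes
  spf <- serialize_data_record(data_record(3, "SPF", data = as.raw(1), tfid = 9))
  expect_identical(spf[7:10], as.raw(c(0, 0, 0, 9)))
  expect_length(spf, 11)
  expect_identical(spf[6], as.raw(2)) # SM code for SPF
  # tool record: 1 + 4 + payload
  expect_length(serialize_tool_record(tool_record(2, rand_raw(100))), 105)
})

test_that("serialize/parse round-trips randomized records of both types", {
  withr::with_seed(31, {
    for (i in 1:20) {
      fid <- sample(0:100000, 1)
      sm <- sample(c("OF", "CPF", "SPF"), 1)
      d <- rand_raw(sample(0:200, 1))
      r <- switch(sm,
                  OF = data_record(fid, "OF", data = d),
                  CPF = data_record(fid, "CPF", data = d, tool = rand_raw(sample(0:100, 1))),
                  SPF = data_record(fid, "SPF", data = d, tfid = sample(0:999, 1)))
      expect_identical(parse_data_record(serialize_data_record(r)), r)
      t <- tool_record(sample(0:100000, 1), rand_raw(sample(0:300, 1)))
      expect_identical(parse_tool_record(serialize_tool_record(t)), t)
    }
  })
})

test_that("malformed byte strings raise the advertised errors", {
  expect_error(parse_data_record(as.raw(1:9)), "underflow")
  bad_sm <- serialize_data_record(data_record(1, "OF"))
  bad_sm[6] <- as.raw(7)
  expect_error(parse_data_record(bad_sm), "unknown SM")
  expect_error(parse_tool_record(serialize_data_record(data_record(1, "OF"))),
               "expected 1")
  expect_error(parse_data_record(serialize_tool_record(tool_record(1, rand_raw(8)))),
               "expected 0")
  expect_error(data_record(2^32, "OF"), "4-byte")
})

test_that("split_by_file_type separates records, preserving order", {
  d1 <- serialize_data_record(data_record(1, "OF", data = as.raw(1)))
  d2 <- serialize_data_record(data_record(2, "OF", data = as.raw(2)))
  t1 <- serialize_tool_record(tool_record(9, rand_raw(4)))
  set <- split_by_file_type(list(d1, t1, d2))
  expect_length(set$datafiles, 2)
  expect_length(set$toolfiles, 1)
  expect_equal(vapply(set$datafiles, `[[`, numeric(1), "fid"), c(1, 2))
  empty <- split_by_file_type(list())
  expect_length(empty$datafiles, 0)
  expect_length(empty$toolfiles, 0)
  expect_error(split_by_file_type(list(as.raw(c(7, 7)))), "index 1")
})

test_that("read_file follows the OF / CPF / SPF branches of the read procedure", {
  reg <- tool_registry(c("9" = "gzip"))
  payload <- charToRaw(strrep("x", 1000))
  compressed <- reg[["9"]]$compress(payload)
  records <- list(
    serialize_data_record(data_record(1, "OF", data = charToRaw("hello"))),
    serialize_data_record(data_record(2, "SPF", data = compressed, tfid = 9)),
    serialize_data_record(data_record(3, "CPF", data = compressed,
                                      tool = rand_raw(50))),
    serialize_tool_record(tool_record(9, rand_raw(80)))
  )
  set <- split_by_file_type(records)
  expect_identical(read_file(1, set, reg), charToRaw("hello"))
  expect_identical(read_file(2, set, reg), payload)
  expect_identical(read_file(3, set, reg, cpf_tools = c("3" = 9)), payload)
  expect_error(read_file(999, set, reg), "not found")
  # SPF pointing at a missing tool
  dangling <- split_by_file_type(records[1:2])
  expect_error(read_file(2, dangling, reg), "dangling tool")
  # tool present but not registered
  expect_error(read_file(2, set, tool_registry(c("8" = "gzip"))), "unknown tool")
  expect_error(read_file(3, set, reg), "no tool mapping")
})

test_that("k files sharing a tool keep exactly one TD copy in a separate-storage set", {
  reg <- tool_registry(c("9" = "xz"))
  tool_bytes <- rand_raw(400)
  k <- 4
  spf <- lapply(seq_len(k), function(i) {
    serialize_data_record(data_record(i, "SPF",
                                      data = reg[["9"]]$compress(rand_raw(100)),
                                      tfid = 9))
  })
  blobs <- c(spf, list(serialize_tool_record(tool_record(9, tool_bytes))))
  total <- sum(vapply(blobs, length, numeric(1)))
  spf_payload <- sum(vapply(spf, length, numeric(1)))
  # the set's bytes contain the tool exactly once: total = SPF bytes + 5 + |TD|
  expect_equal(total - spf_payload, 5 + length(tool_bytes))
  set <- split_by_file_type(blobs)
  for (i in seq_len(k)) expect_silent(read_file(i, set, reg))
})
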