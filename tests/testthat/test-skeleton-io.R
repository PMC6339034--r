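# skeleton definitions, position CSV round trips, BVH parsing

test_that("skeleton validation enforces the tree structure", {
  sk <- skeleton_definition(c("a", "b", "c", "d"), c(NA, 1, 1, 3))
  expect_s3_class(sk, "rg_skeleton")
  expect_equal(nrow(sk$bones), 3L)                  # J - 1 bones
  expect_equal(sk$bones[, "child"], c(2L, 3L, 4L), ignore_attr = TRUE)
  expect_error(skeleton_definition(c("a", "b"), c(NA, NA)),
               class = "riemgait_error_argument")   # two roots
  expect_error(skeleton_definition(c("a", "b", "c"), c(NA, 3, 2)),
               class = "riemgait_error_argument")   # cycle
  expect_error(skeleton_definition(c("a", "a"), c(NA, 1)),
               class = "riemgait_error_argument")   # duplicate names
})

test_that("skeleton JSON round trips", {
  sk <- skeleton_definition(c("root", "l", "r"), c(NA, 1, 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_skeleton_json(sk, path)
  sk2 <- read_skeleton_json(path)
  expect_equal(sk2$joints, sk$joints)
  expect_equal(sk2$parents, sk$parents)
})

test_that("position CSV writes the documented layout and round trips", {
  sk <- chain_skeleton()
  set.seed(42)
  pos <- array(rnorm(5 * 3 * 3), c(5, 3, 3))
  sq <- joint_sequence(pos, sk, frame_rate = 60, subject_label = "s1",
                       sequence_id = "trial_a")
  path <- withr::local_tempfile(fileext = ".csv")
  write_position_csv(sq, sk, path)
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_length(hdr, 1 + 3 * 3)                     # frame + xyz per joint
  expect_equal(hdr[1:4], c("frame", "root_x", "root_y", "root_z"))
  expect_equal(length(readLines(path)) - 1L, 5L)    # F data rows
  back <- read_position_csv(path, sk)
  expect_lt(max(abs(back$positions - sq$positions)), 1e-12)
  expect_equal(back$subject_label, "s1")            # via sidecar
  expect_equal(back$frame_rate, 60)
  expect_equal(back$sequence_id, "trial_a")
})

test_that("position CSV validation names the offending column and row", {
  sk <- chain_skeleton()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,root_x,root_y,root_z,mid_x,mid_y,mid_z,tip_x,tip_y",
               "0,0,0,0,1,0,0,2,0"), path)
  expect_error(read_position_csv(path, sk), "tip_z",
               class = "riemgait_error_format")
  writeLines(c("frame,root_x,root_y,root_z,mid_x,mid_y,mid_z,tip_x,tip_y,tip_z",
               "0,0,0,0,1,0,0,2,0,0",
               "1,0,0,oops,1,0,0,2,0,0"), path)
  expect_error(read_position_csv(path, sk), "row 2",
               class = "riemgait_error_parse")
})

write_bvh_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bvh",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

bvh_single_bone <- function(motion_rows,
                            channels = "CHANNELS 3 Zrotation Xrotation Yrotation",
                            frames = length(motion_rows)) {
  c("HIERARCHY",
    "ROOT hips",
    "{",
    "  OFFSET 0 0 0",
    paste0("  ", channels),
    "  JOINT chest",
    "  {",
    "    OFFSET 0 10 0",
    "    End Site",
    "    {",
    "      OFFSET 10 0 0",
    "    }",
    "  }",
    "}",
    "MOTION",
    paste("Frames:", frames),
    "Frame Time: 0.04",
    motion_rows)
}

test_that("BVH with zero rotations reproduces cumulative offsets", {
  path <- write_bvh_fixture(bvh_single_bone(c("0 0 0", "0 0 0")))
  out <- read_bvh(path)
  expect_equal(out$skeleton$joints, c("hips", "chest", "chest_end"))
  expect_equal(out$sequence$frame_rate, 25)
  expect_equal(out$sequence$positions[1, "chest", ], c(x = 0, y = 10, z = 0))
  expect_equal(out$sequence$positions[2, "chest_end", ],
               c(x = 10, y = 10, z = 0))
})

test_that("BVH applies right-handed Euler rotations in channel order", {
  # 90 degree Z rotation of the root sends the x-offset child to +y
  path <- write_bvh_fixture(c(
    "HIERARCHY", "ROOT hips", "{", "  OFFSET 0 0 0",
    "  CHANNELS 3 Zrotation Xrotation Yrotation",
    "  JOINT arm", "  {", "    OFFSET 10 0 0",
    "    End Site", "    {", "      OFFSET 1 0 0", "    }",
    "  }", "}",
    "MOTION", "Frames: 2", "Frame Time: 0.02",
    "90 0 0", "90 0 0"))
  out <- read_bvh(path)
  expect_equal(out$sequence$positions[1, "arm", ], c(x = 0, y = 10, z = 0),
               tolerance = 1e-12)
})

test_that("BVH rejects malformed and unsupported input", {
  path <- write_bvh_fixture(bvh_single_bone("0 0 0", frames = 2))
  expect_error(read_bvh(path), class = "riemgait_error_format")  # truncated
  path2 <- write_bvh_fixture(bvh_single_bone(
    c("0 0 0 0", "0 0 0 0"),
    channels = "CHANNELS 4 Zrotation Xrotation Yrotation Wscale"))
  expect_error(read_bvh(path2), class = "riemgait_error_unsupported")
})
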