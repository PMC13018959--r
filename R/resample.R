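# Trilinear resampling of a 3D array at arbitrary world coordinates.
# Interpolation weights within 1e-9 of the lattice are snapped to 0/1 so that
# lattice-preserving transforms (identity, integer-voxel translations)
# reproduce array values bit-exactly.

world_coords <- function(d, spacing, origin) {
  list(x = array(origin[1] + (seq_len(d[1]) - 1) * spacing[1], d),
       y = array(rep(origin[2] + (seq_len(d[2]) - 1) * spacing[2],
                     each = d[1]), d),
       z = array(rep(origin[3] + (seq_len(d[3]) - 1) * spacing[3],
                     each = d[1] * d[2]), d))
}

resample_trilinear <- function(data, spacing, origin, px, py, pz, fill = 0) {
  d <- dim(data)
  fx <- (px - origin[1]) / spacing[1] + 1
  fy <- (py - origin[2]) / spacing[2] + 1
  fz <- (pz - origin[3]) / spacing[3] + 1
  snap <- function(f) { r <- round(f); f[abs(f - r) < 1e-9] <- r[abs(f - r) < 1e-9]; f }
  fx <- snap(fx); fy <- snap(fy); fz <- snap(fz)
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  inside <- fx >= 1 & fx <= d[1] & fy >= 1 & fy <= d[2] & fz >= 1 & fz <= d[3]
  # clamp corner indices so the gather is always valid; outside voxels are
  # overwritten with `fill` afterwards
  cl <- function(i, n) pmin(pmax(i, 1), n)
  i0c <- cl(i0, d[1]); i1c <- cl(i0 + 1, d[1])
  j0c <- cl(j0, d[2]); j1c <- cl(j0 + 1, d[2])
  k0c <- cl(k0, d[3]); k1c <- cl(k0 + 1, d[3])
  lin <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  v <- (1 - wx) * (1 - wy) * (1 - wz) * data[lin(i0c, j0c, k0c)] +
       wx * (1 - wy) * (1 - wz) * data[lin(i1c, j0c, k0c)] +
       (1 - wx) * wy * (1 - wz) * data[lin(i0c, j1c, k0c)] +
       wx * wy * (1 - wz) * data[lin(i1c, j1c, k0c)] +
       (1 - wx) * (1 - wy) * wz * data[lin(i0c, j0c, k1c)] +
       wx * (1 - wy) * wz * data[lin(i1c, j0c, k1c)] +
       (1 - wx) * wy * wz * data[lin(i0c, j1c, k1c)] +
       wx * wy * wz * data[lin(i1c, j1c, k1c)]
  v[!inside] <- fill
  array(v, dim(px))
}
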