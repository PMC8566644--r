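# Frozen per-configuration triangle table for the marching-cubes surface
# mesher. Index: cube configuration 0..255, bit b set when corner
# (b&1, (b>>1)&1, (b>>2)&1) lies inside the mask. Coordinates are in
# cube-local voxel units; vertices of binary masks fall on edge midpoints.

.mcTriCount <- c(0,1,1,2,1,2,4,3,1,4,2,3,2,3,3,2,1,2,4,3,4,3,9,4,2,5,5,4,5,4,4,3,1,4,2,3,2,5,5,4,4,9,3,4,5,4,4,3,2,3,3,2,5,4,4,3,5,4,4,3,4,9,9,2,1,4,2,5,2,3,5,4,4,9,5,4,3,4,4,3,2,3,5,4,3,2,4,3,5,4,4,9,4,3,9,2,4,9,5,4,5,4,4,9,9,4,4,3,4,3,9,2,3,4,4,3,4,3,9,2,4,3,9,2,9,2,2,1,1,2,4,5,4,5,9,4,2,5,3,4,3,4,4,3,4,5,9,4,9,4,4,3,5,4,4,9,4,9,3,2,2,5,3,4,5,4,4,9,3,4,2,3,4,9,3,2,3,4,4,3,4,9,3,2,4,9,3,2,9,2,2,1,2,5,5,4,3,4,4,9,3,4,4,9,2,3,3,2,3,4,4,9,4,3,3,2,4,9,9,2,3,2,2,1,3,4,4,9,4,9,9,2,4,3,3,2,3,2,2,1,2,3,3,2,3,2,2,1,3,2,2,1,2,1,1,0)

.mcTriCoords <- c(
  0.0,0.5,0.0,0.5,0.0,0.0,0.0,0.0,0.5,0.5,0.0,0.0,1.0,0.5,0.0,1.0,0.0,0.5,0.0,
  0.0,0.5,0.0,0.5,0.0,1.0,0.0,0.5,1.0,0.0,0.5,0.0,0.5,0.0,1.0,0.5,0.0,0.0,1.0,
  0.5,0.5,1.0,0.0,0.0,0.5,0.0,0.0,1.0,0.5,0.5,1.0,0.0,0.0,0.0,0.5,0.0,0.0,0.5,
  0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,0.0,1.0,0.5,0.0,0.0,1.0,0.5,1.0,0.5,0.0,1.0,
  0.0,0.5,0.0,1.0,0.5,0.5,0.0,0.0,0.0,0.5,0.0,0.0,1.0,0.5,0.5,0.0,0.0,0.0,1.0,
  0.5,1.0,0.0,0.5,1.0,0.5,0.0,1.0,0.0,0.5,0.5,1.0,0.0,1.0,0.0,0.5,0.0,1.0,0.5,
  0.5,1.0,0.0,1.0,0.0,0.5,0.0,0.0,0.5,0.0,1.0,0.5,0.5,1.0,0.0,1.0,1.0,0.5,1.0,
  0.5,0.0,1.0,0.5,0.0,0.5,0.0,0.0,1.0,1.0,0.5,0.5,0.0,0.0,0.0,0.0,0.5,1.0,1.0,
  0.5,0.0,0.5,0.0,0.5,1.0,0.0,1.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,0.0,0.0,0.5,
  1.0,0.0,0.5,0.5,0.0,0.0,1.0,1.0,0.5,1.0,1.0,0.5,0.5,0.0,0.0,0.5,1.0,0.0,0.5,
  1.0,0.0,1.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,0.0,0.0,0.5,0.0,0.5,0.0,1.0,1.0,
  0.5,1.0,0.0,0.5,0.0,0.0,0.5,0.0,0.5,0.0,0.0,1.0,0.5,1.0,0.5,0.0,1.0,0.5,0.0,
  0.0,1.0,0.5,1.0,1.0,0.5,0.5,0.0,0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.0,0.5,1.0,
  1.0,0.5,1.0,0.5,0.0,0.0,0.0,0.5,0.0,1.0,0.5,1.0,1.0,0.5,0.0,0.5,0.0,0.0,1.0,
  0.5,0.5,0.0,0.0,0.0,1.0,0.5,1.0,0.0,0.5,0.5,0.0,0.0,0.0,1.0,0.5,1.0,1.0,0.5,
  1.0,0.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,0.0,0.0,0.5,0.0,1.0,0.5,1.0,1.0,0.5,1.0,
  0.0,0.5,0.5,0.0,1.0,0.0,0.5,1.0,0.0,0.0,0.5,0.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,
  1.0,0.0,0.5,1.0,0.5,0.0,0.0,0.5,0.0,1.0,1.0,0.0,0.5,0.5,0.0,1.0,1.0,0.5,0.0,
  0.5,0.0,1.0,0.0,0.5,1.0,1.0,0.5,0.0,0.0,0.0,0.5,0.5,0.0,0.0,1.0,0.5,0.0,0.0,
  0.0,0.5,1.0,0.5,0.0,0.0,0.5,1.0,0.5,0.0,1.0,0.0,0.5,1.0,1.0,0.0,0.5,0.0,0.5,
  1.0,1.0,0.5,0.0,1.0,0.0,0.5,0.0,0.5,1.0,0.0,0.5,0.0,1.0,0.5,0.0,0.0,0.5,0.0,
  0.0,0.0,0.5,0.5,1.0,0.0,0.0,0.0,0.5,0.5,0.0,1.0,0.5,1.0,0.0,0.0,0.5,1.0,0.0,
  1.0,0.5,0.5,1.0,0.0,0.0,0.5,1.0,0.5,1.0,0.0,0.5,0.0,1.0,0.0,1.0,0.5,0.5,1.0,
  0.0,0.0,0.5,1.0,0.5,1.0,0.0,0.5,0.0,1.0,0.0,0.5,1.0,0.5,1.0,0.0,0.5,0.0,0.0,
  0.5,0.0,1.0,0.5,1.0,0.0,1.0,0.5,0.0,0.5,0.0,0.0,1.0,0.0,0.5,0.5,0.0,0.0,1.0,
  0.5,0.0,0.5,0.0,0.0,1.0,0.0,0.5,0.5,0.0,1.0,0.5,0.0,0.0,0.5,0.0,1.0,0.0,0.0,
  0.5,0.0,0.5,1.0,0.0,0.0,0.5,0.5,0.0,1.0,0.0,0.0,0.5,0.0,0.5,1.0,0.0,0.5,0.0,
  0.0,1.0,0.5,0.0,0.5,0.0,0.0,0.5,1.0,0.0,0.5,0.0,0.0,1.0,0.5,0.5,1.0,0.0,0.0,
  0.5,0.0,0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,0.0,1.0,0.5,0.0,1.0,0.0,0.5,0.5,1.0,
  0.0,1.0,0.0,0.5,0.5,0.0,1.0,0.0,1.0,0.5,0.5,1.0,0.0,0.5,0.0,1.0,0.0,0.5,1.0,
  0.0,1.0,0.5,0.5,0.0,1.0,0.5,0.0,1.0,0.0,0.5,1.0,0.0,0.0,0.5,1.0,1.0,0.5,1.0,
  0.5,0.0,0.5,1.0,0.0,0.0,0.5,0.0,0.5,1.0,0.0,0.0,0.5,1.0,1.0,1.0,0.5,0.0,0.5,
  1.0,0.5,1.0,0.0,0.0,0.5,1.0,1.0,1.0,0.5,0.5,0.0,1.0,1.0,0.5,0.0,0.5,0.0,1.0,
  1.0,1.0,0.5,0.5,0.0,1.0,1.0,0.5,0.0,0.5,0.0,0.0,1.0,0.0,0.5,0.5,0.0,1.0,1.0,
  1.0,0.5,0.0,0.5,1.0,1.0,1.0,0.5,0.5,0.0,1.0,1.0,1.0,0.5,0.0,0.5,1.0,0.5,1.0,
  0.0,0.0,0.0,0.5,0.5,1.0,0.0,0.0,0.5,1.0,0.5,1.0,0.0,0.0,0.0,0.5,0.5,0.0,0.0,
  1.0,1.0,0.5,1.0,0.0,0.5,0.5,0.0,1.0,0.0,0.5,0.0,1.0,1.0,0.5,0.5,0.0,1.0,0.0,
  0.5,1.0,0.0,0.5,0.0,0.5,0.0,1.0,1.0,1.0,0.5,0.0,0.5,0.0,0.5,1.0,0.0,0.0,0.5,
  0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,0.0,0.0,0.0,0.5,1.0,0.5,0.0,
  0.5,0.0,1.0,1.0,1.0,0.5,0.0,0.5,1.0,1.0,1.0,0.5,0.5,0.0,1.0,1.0,1.0,0.5,0.0,
  0.5,1.0,0.0,1.0,0.5,0.0,1.0,0.5,1.0,1.0,0.5,0.0,0.5,1.0,1.0,1.0,0.5,0.5,0.0,
  0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.5,0.0,1.0,0.0,0.5,1.0,1.0,1.0,0.5,1.0,0.5,0.0,
  0.5,0.0,0.0,0.5,0.0,0.0,0.0,0.5,0.0,0.0,0.0,0.5,0.0,1.0,0.5,0.5,0.0,1.0,0.0,
  0.5,1.0,0.5,0.0,1.0,0.0,1.0,0.5,1.0,0.0,0.5,1.0,1.0,0.5,1.0,0.0,0.5,0.0,1.0,
  0.5,1.0,0.0,0.5,0.5,0.0,1.0,0.0,0.5,1.0,0.0,1.0,0.5,1.0,0.0,0.5,0.0,0.5,1.0,
  1.0,1.0,0.5,1.0,0.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,1.0,0.5,1.0,0.5,0.0,1.0,0.5,
  0.0,0.0,1.0,0.0,0.5,0.0,0.5,0.0,1.0,0.0,0.5,1.0,0.5,1.0,0.0,0.5,0.0,0.5,0.0,
  1.0,0.0,0.0,0.5,0.0,0.5,0.0,0.5,0.0,1.0,0.0,0.5,0.0,1.0,0.5,1.0,0.5,0.0,0.0,
  1.0,0.5,0.0,0.5,0.0,1.0,0.5,0.0,1.0,1.0,0.5,0.0,1.0,0.5,1.0,0.0,0.0,0.5,0.0,
  0.5,0.0,0.5,0.0,1.0,0.0,0.5,0.0,1.0,0.5,1.0,0.5,0.0,1.0,0.0,0.5,0.0,1.0,0.5,
  0.0,1.0,0.5,1.0,1.0,0.0,0.5,1.0,0.5,1.0,0.5,0.0,1.0,0.5,1.0,0.0,0.0,0.5,0.0,
  0.0,1.0,0.5,0.0,1.0,0.5,0.5,0.0,1.0,0.0,0.0,0.5,0.5,0.0,1.0,0.0,1.0,0.5,1.0,
  0.5,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.0,
  0.5,0.5,0.0,0.0,1.0,0.0,0.5,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.5,0.0,
  0.5,1.0,0.0,1.0,0.5,1.0,0.0,1.0,0.5,0.5,0.0,1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.0,
  1.0,0.5,0.5,0.0,1.0,0.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,
  0.0,1.0,0.5,1.0,0.5,0.0,1.0,0.0,1.0,0.5,1.0,0.5,0.0,0.5,0.0,1.0,0.0,0.0,0.5,
  0.0,1.0,0.5,0.5,0.0,1.0,0.5,1.0,0.0,1.0,0.5,0.0,0.0,1.0,0.5,1.0,1.0,0.5,1.0,
  0.5,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.5,0.0,1.0,0.5,1.0,0.0,1.0,0.0,0.5,1.0,0.5,
  0.0,0.5,1.0,0.0,1.0,0.0,0.5,0.5,1.0,0.0,0.5,0.0,1.0,0.5,0.0,0.0,0.0,0.5,0.0,
  0.5,1.0,0.0,0.0,0.5,0.0,0.5,0.0,0.0,0.0,0.0,0.5,0.5,0.0,1.0,0.0,0.0,0.5,0.5,
  0.0,0.0,1.0,0.0,0.5,0.5,0.0,1.0,0.5,0.0,0.0,0.5,0.0,1.0,1.0,0.0,0.5,1.0,0.5,
  1.0,1.0,0.5,0.0,1.0,0.5,1.0,1.0,0.0,0.5,1.0,0.5,1.0,1.0,0.5,0.0,1.0,1.0,0.5,
  0.5,1.0,0.0,1.0,1.0,0.5,1.0,0.5,0.0,0.5,0.0,0.0,0.5,1.0,0.0,1.0,0.5,0.0,1.0,
  0.5,1.0,0.5,0.0,1.0,1.0,1.0,0.5,0.5,0.0,1.0,0.5,1.0,0.0,1.0,1.0,0.5,0.5,0.0,
  1.0,0.5,0.0,0.0,0.5,1.0,0.0,0.5,1.0,0.0,1.0,1.0,0.5,0.0,0.5,0.0,0.0,0.5,0.0,
  1.0,1.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,1.0,0.5,1.0,0.0,0.0,0.5,1.0,0.5,1.0,0.5,
  0.0,1.0,0.0,0.0,0.5,0.0,0.5,0.0,1.0,0.0,0.5,1.0,0.5,0.0,1.0,0.0,0.5,0.0,0.5,
  0.0,0.5,0.0,1.0,0.0,1.0,0.5,0.5,0.0,1.0,0.0,0.5,0.0,0.5,0.0,1.0,0.0,1.0,0.5,
  1.0,0.5,1.0,1.0,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.0,0.5,1.0,0.5,0.0,0.5,
  0.0,0.0,1.0,0.5,1.0,0.5,0.0,1.0,1.0,1.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,0.5,0.0,
  1.0,1.0,1.0,0.5,0.0,0.0,0.5,0.0,1.0,0.5,0.5,0.0,1.0,0.5,0.0,0.0,1.0,0.5,1.0,
  0.5,0.0,0.0,0.0,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.5,1.0,1.0,0.5,1.0,0.5,1.0,0.0,
  1.0,0.5,0.5,0.0,0.0,0.0,0.5,0.0,1.0,1.0,0.5,1.0,0.5,1.0,0.5,0.0,1.0,0.0,0.0,
  0.5,1.0,1.0,0.5,0.5,0.0,1.0,0.0,1.0,0.5,1.0,1.0,0.5,0.0,0.0,0.5,1.0,0.0,0.5,
  1.0,0.5,1.0,0.0,0.0,0.5,0.0,0.0,0.5,1.0,0.5,1.0,0.0,0.5,1.0,1.0,0.0,0.5,1.0,
  0.5,1.0,0.5,0.0,0.0,1.0,0.5,1.0,0.0,0.5,0.0,0.5,0.0,0.0,1.0,0.5,1.0,0.0,0.5,
  1.0,0.0,0.5,0.0,0.5,0.0,0.0,1.0,0.5,0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.5,1.0,
  0.0,0.0,0.5,1.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,1.0,0.0,0.5,0.0,1.0,0.5,1.0,0.0,
  0.5,1.0,1.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,0.0,1.0,0.5,1.0,0.5,
  1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.0,0.5,
  0.0,0.5,0.0,1.0,0.0,0.5,0.5,1.0,0.0,1.0,0.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,1.0,
  0.5,1.0,0.0,0.5,1.0,0.0,1.0,0.5,0.5,0.0,0.0,1.0,0.5,1.0,0.0,1.0,0.5,0.5,1.0,
  0.0,0.5,0.0,0.0,0.0,1.0,0.5,1.0,0.5,1.0,0.5,0.0,0.0,1.0,0.0,0.5,0.0,0.5,0.0,
  0.0,0.0,0.5,0.5,0.0,0.0,0.0,1.0,0.5,0.5,1.0,0.0,0.0,0.5,1.0,1.0,0.5,0.0,0.0,
  0.5,1.0,0.5,1.0,0.0,0.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,1.0,0.0,1.0,
  0.5,0.5,1.0,0.0,1.0,0.5,0.0,0.0,0.5,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.0,0.5,1.0,
  1.0,0.5,0.0,0.0,0.5,1.0,1.0,1.0,0.5,1.0,0.5,1.0,1.0,1.0,0.5,0.0,0.5,1.0,0.5,
  1.0,0.0,0.0,0.0,0.5,0.5,1.0,0.0,0.0,0.5,1.0,0.5,1.0,0.0,0.0,0.0,0.5,1.0,0.5,
  0.0,1.0,0.0,0.5,1.0,0.5,0.0,0.0,0.0,0.5,0.5,0.0,0.0,1.0,0.0,0.5,1.0,0.5,0.0,
  1.0,0.5,1.0,0.5,1.0,0.0,1.0,1.0,0.5,0.5,1.0,0.0,1.0,0.5,1.0,0.0,0.5,0.0,0.0,
  0.5,1.0,0.0,0.5,0.0,1.0,0.5,1.0,0.5,0.0,0.0,0.5,1.0,0.0,0.0,0.0,0.5,0.5,1.0,
  0.0,1.0,0.5,1.0,0.0,0.0,0.5,1.0,0.5,1.0,0.0,0.5,1.0,0.0,0.0,0.5,0.5,1.0,0.0,
  1.0,1.0,0.5,1.0,0.5,1.0,0.0,0.5,0.0,0.5,1.0,0.0,1.0,1.0,0.5,1.0,0.5,1.0,0.0,
  0.5,0.0,1.0,1.0,0.5,0.0,0.5,1.0,0.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,1.0,0.0,1.0,
  0.5,1.0,0.5,1.0,1.0,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.0,0.5,0.0,0.5,0.0,
  0.0,0.0,0.5,0.0,0.5,0.0,1.0,0.0,0.5,1.0,0.5,0.0,1.0,1.0,0.5,0.5,0.5,0.5,0.0,
  1.0,0.5,0.5,0.5,0.5,1.0,0.5,0.0,0.0,1.0,0.5,0.5,0.0,0.0,0.0,1.0,0.5,1.0,0.5,
  0.0,0.0,1.0,0.5,0.5,0.0,0.0,0.0,0.5,1.0,1.0,0.0,0.5,0.0,0.5,1.0,0.5,0.0,0.0,
  0.0,0.5,1.0,1.0,0.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,1.0,0.5,1.0,0.0,0.5,1.0,1.0,
  1.0,0.5,1.0,0.5,1.0,0.5,0.5,0.5,0.5,0.5,0.5,1.0,0.0,0.5,1.0,0.5,0.0,1.0,1.0,
  0.5,0.5,0.5,0.5,0.0,1.0,0.5,1.0,1.0,0.5,0.0,0.5,0.0,0.5,0.5,0.5,0.0,0.5,0.0,
  1.0,1.0,0.5,0.5,0.0,0.0,1.0,0.5,1.0,0.5,0.0,0.0,1.0,1.0,0.5,0.5,0.0,0.0,1.0,
  0.5,1.0,0.0,0.0,0.5,0.5,0.5,0.5,0.0,0.0,0.5,1.0,0.5,1.0,1.0,0.5,1.0,0.0,0.5,
  1.0,0.5,0.5,0.5,0.5,0.5,0.5,0.0,0.5,1.0,0.0,1.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,
  0.5,0.5,0.5,1.0,1.0,0.5,1.0,0.5,1.0,0.0,0.5,1.0,1.0,1.0,0.5,0.0,0.5,1.0,0.0,
  1.0,0.5,0.5,1.0,1.0,0.0,1.0,0.5,0.0,0.5,1.0,0.0,1.0,0.5,0.0,0.5,0.0,0.5,1.0,
  1.0,0.0,0.5,0.0,0.5,0.0,0.0,0.5,1.0,1.0,0.0,0.0,0.5,0.0,0.5,1.0,0.5,1.0,1.0,
  0.0,0.0,0.5,0.5,1.0,1.0,0.5,0.0,0.0,0.5,1.0,1.0,0.0,1.0,0.5,0.0,0.5,1.0,1.0,
  0.5,0.0,1.0,0.0,0.5,0.5,0.0,0.0,0.0,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,0.5,1.0,
  1.0,1.0,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,0.5,1.0,1.0,1.0,0.5,0.0,0.0,1.0,0.5,
  1.0,0.5,0.0,0.5,1.0,1.0,1.0,0.5,0.0,0.0,1.0,0.5,0.0,0.5,0.0,0.0,0.5,1.0,0.5,
  1.0,1.0,0.0,0.5,0.0,0.0,0.5,0.0,0.5,1.0,1.0,0.5,1.0,0.0,0.0,0.5,1.0,0.5,1.0,
  1.0,0.0,0.0,0.5,0.5,1.0,1.0,0.5,0.0,0.0,0.0,0.0,0.5,0.5,1.0,1.0,0.5,1.0,0.0,
  0.5,0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,1.0,1.0,
  0.0,0.5,0.5,1.0,1.0,1.0,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,0.5,1.0,1.0,1.0,0.5,
  0.0,0.5,1.0,0.0,1.0,0.5,0.0,0.5,1.0,1.0,0.5,1.0,1.0,0.5,1.0,0.0,0.0,0.5,1.0,
  0.5,1.0,0.0,1.0,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,0.0,0.0,0.5,0.0,0.5,1.0,1.0,
  0.0,0.5,0.5,1.0,0.0,1.0,0.5,0.0,0.5,1.0,0.0,0.0,1.0,0.5,1.0,0.5,0.0,0.0,1.0,
  0.5,0.0,0.5,1.0,1.0,0.5,0.0,0.5,1.0,1.0,1.0,1.0,0.5,1.0,0.5,0.0,0.5,1.0,1.0,
  1.0,0.5,0.0,0.0,0.5,1.0,0.5,1.0,1.0,1.0,1.0,0.5,0.5,1.0,0.0,1.0,0.5,0.0,0.5,
  1.0,0.0,1.0,1.0,0.5,0.5,1.0,0.0,1.0,0.5,0.0,0.5,0.0,0.0,0.5,1.0,0.0,0.5,0.0,
  0.0,0.0,0.5,0.0,0.0,0.0,0.5,0.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,0.0,0.0,0.0,0.5,
  0.0,1.0,0.5,0.0,0.5,1.0,0.0,1.0,0.5,0.0,0.0,0.5,0.0,1.0,0.5,0.0,0.5,1.0,0.5,
  1.0,1.0,0.0,1.0,0.5,0.5,1.0,1.0,0.5,1.0,0.0,1.0,0.0,0.5,0.5,1.0,1.0,1.0,1.0,
  0.5,0.5,1.0,1.0,1.0,0.0,0.5,0.0,0.5,1.0,0.5,0.0,0.0,0.0,0.5,1.0,1.0,0.0,0.5,
  0.0,0.5,1.0,0.5,0.0,0.0,0.0,1.0,0.5,0.5,1.0,0.0,0.0,1.0,0.5,0.5,0.0,0.0,0.0,
  1.0,0.5,0.0,0.5,0.0,0.5,1.0,0.0,0.0,0.5,1.0,0.5,1.0,1.0,0.0,0.0,0.5,1.0,1.0,
  0.5,0.0,0.0,0.5,0.5,1.0,1.0,0.0,0.0,0.5,1.0,1.0,0.5,1.0,0.0,0.5,1.0,1.0,0.5,
  1.0,0.5,0.0,0.5,1.0,1.0,1.0,0.5,0.0,0.0,0.5,1.0,0.5,1.0,1.0,1.0,0.5,0.0,0.0,
  0.5,0.0,0.0,0.5,1.0,1.0,1.0,0.5,1.0,0.5,0.0,0.5,1.0,1.0,0.5,1.0,1.0,1.0,0.5,
  0.0,0.0,0.5,1.0,1.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.0,0.0,0.5,
  0.0,0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.0,0.5,1.0,1.0,1.0,0.5,0.5,
  0.0,0.0,1.0,1.0,0.5,1.0,0.0,0.5,0.5,0.0,0.0,0.0,0.5,1.0,0.5,1.0,1.0,1.0,1.0,
  0.5,0.0,0.0,0.5,0.0,0.5,1.0,0.5,1.0,1.0,1.0,1.0,0.5,0.0,0.0,0.5,0.5,1.0,1.0,
  1.0,0.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,0.5,1.0,1.0,0.0,1.0,0.5,0.5,0.0,1.0,0.5,
  0.0,1.0,0.0,1.0,0.5,0.0,0.0,0.5,0.0,0.5,0.0,0.5,0.0,0.0,0.0,1.0,0.5,0.5,0.0,
  0.0,0.5,1.0,1.0,0.0,1.0,0.5,0.5,0.0,0.0,0.5,0.0,1.0,0.5,1.0,1.0,0.0,0.0,0.5,
  0.5,0.0,0.0,0.0,1.0,0.5,1.0,0.5,0.0,0.0,1.0,0.5,0.5,0.0,0.0,0.0,1.0,0.5,1.0,
  0.5,0.0,0.5,1.0,1.0,1.0,0.0,0.5,0.5,1.0,1.0,1.0,0.5,0.0,0.5,1.0,1.0,1.0,0.0,
  0.5,0.5,0.0,1.0,0.5,0.0,1.0,0.5,1.0,1.0,0.0,1.0,0.5,1.0,0.5,0.0,0.5,0.0,1.0,
  0.0,1.0,0.5,0.0,0.5,0.0,1.0,0.5,0.0,0.0,1.0,0.5,1.0,0.0,0.5,0.5,0.0,1.0,1.0,
  0.5,0.0,0.0,0.0,0.5,0.5,0.0,1.0,0.0,0.5,0.0,0.5,0.0,1.0,0.5,1.0,0.0,0.0,0.5,
  0.0,0.5,0.0,1.0,0.5,1.0,1.0,0.5,1.0,0.0,0.5,1.0,1.0,0.5,0.0,0.0,0.5,0.0,1.0,
  0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,0.0,0.0,0.0,0.5,0.0,0.0,0.0,0.5,1.0,
  0.5,0.0,1.0,0.0,0.5,0.5,1.0,0.0,0.5,0.0,1.0,0.5,1.0,0.0,1.0,0.0,0.5,0.5,1.0,
  0.0,0.5,0.0,1.0,0.5,1.0,1.0,0.5,1.0,0.0,1.0,0.5,0.0,1.0,0.0,0.5,0.5,0.0,1.0,
  0.5,1.0,0.0,1.0,0.0,0.5,0.5,1.0,1.0,0.5,1.0,0.0,0.5,0.0,1.0,0.0,0.0,0.5,0.5,
  1.0,0.0,0.0,1.0,0.5,0.5,1.0,0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,
  0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.5,0.0,1.0,1.0,1.0,0.5,0.5,1.0,1.0,1.0,1.0,0.5,
  0.5,0.0,1.0,0.5,1.0,0.0,0.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,1.0,0.5,0.0,0.5,
  1.0,1.0,0.5,0.0,0.0,0.5,1.0,1.0,1.0,0.5,0.0,0.5,1.0,1.0,0.5,0.0,0.0,0.5,0.0,
  1.0,0.5,1.0,0.0,0.0,0.0,0.5,0.5,0.0,0.0,0.0,0.0,0.5,0.5,1.0,0.0,0.0,1.0,0.5,
  1.0,0.0,0.5,0.5,0.0,1.0,1.0,1.0,0.5,0.5,1.0,1.0,1.0,1.0,0.5,0.5,0.0,1.0,1.0,
  0.0,0.5,0.5,0.5,0.5,1.0,1.0,0.5,1.0,0.0,0.5,0.5,1.0,0.0,0.5,0.5,0.5,0.5,1.0,
  0.0,1.0,0.0,0.5,0.0,0.5,0.0,0.5,0.0,1.0,0.0,0.5,0.0,1.0,0.0,0.5,0.0,0.5,0.0,
  0.5,0.0,1.0,0.0,1.0,0.5,0.5,0.5,0.5,0.0,1.0,0.5,0.5,0.0,1.0,0.5,0.0,1.0,0.5,
  1.0,1.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,1.0,1.0,1.0,1.0,0.5,0.5,1.0,0.0,0.0,1.0,
  0.5,0.5,0.5,0.5,1.0,0.5,0.0,0.0,0.5,0.0,0.0,0.0,0.5,0.5,1.0,1.0,1.0,0.5,0.0,
  0.0,0.0,0.5,0.5,0.0,1.0,0.5,1.0,1.0,0.0,0.0,0.5,1.0,0.5,0.0,0.5,1.0,1.0,1.0,
  1.0,0.5,0.5,1.0,1.0,1.0,1.0,0.5,1.0,0.5,0.0,0.5,0.0,0.0,0.5,1.0,1.0,1.0,0.5,
  0.0,0.5,0.0,1.0,0.5,1.0,1.0,0.5,0.0,0.0,1.0,0.0,0.5,0.5,0.5,0.5,1.0,1.0,0.5,
  0.5,0.5,0.5,0.5,0.0,0.0,1.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,0.5,0.0,0.0,1.0,
  1.0,0.5,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.0,0.5,0.5,1.0,1.0,0.0,0.5,0.0,0.5,1.0,
  1.0,0.0,0.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.0,1.0,0.5,1.0,1.0,1.0,0.0,0.5,
  0.5,0.0,1.0,0.5,0.5,0.5,0.5,0.5,0.5,0.0,0.0,0.5,0.5,0.0,0.0,1.0,0.0,0.5,0.5,
  0.0,1.0,0.5,1.0,1.0,1.0,0.0,0.5,0.5,1.0,1.0,1.0,1.0,0.5,1.0,0.5,1.0,0.5,1.0,
  1.0,1.0,0.0,0.5,0.5,1.0,1.0,0.0,1.0,0.5,1.0,0.0,0.5,0.0,0.5,1.0,0.5,0.0,1.0,
  1.0,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,0.0,1.0,0.5,0.5,0.0,0.0,1.0,0.0,0.5,0.5,
  0.0,1.0,1.0,0.5,1.0,0.5,0.0,1.0,1.0,0.0,0.5,0.5,0.0,1.0,1.0,0.5,1.0,0.5,1.0,
  1.0,0.5,0.0,1.0,0.5,1.0,1.0,0.0,0.5,1.0,0.0,1.0,0.5,0.0,0.5,1.0,0.5,1.0,1.0,
  0.0,0.5,1.0,0.0,1.0,0.5,0.0,0.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,0.0,1.0,0.5,0.0,
  0.0,0.5,0.0,0.5,0.0,0.5,0.0,0.0,0.0,0.0,0.5,0.5,0.0,0.0,0.5,0.0,1.0,1.0,0.5,
  1.0,0.5,1.0,1.0,1.0,0.5,0.0,0.0,1.0,0.5,1.0,0.5,0.0,0.5,1.0,1.0,1.0,0.5,0.0,
  0.0,1.0,0.5,0.5,0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.0,1.0,0.5,0.5,0.0,0.0,0.0,
  0.5,1.0,0.5,0.0,1.0,0.5,0.0,1.0,0.0,0.0,0.5,0.0,0.5,1.0,0.0,0.5,0.0,0.5,1.0,
  1.0,0.0,1.0,0.5,0.5,1.0,1.0,0.0,0.5,0.0,1.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,1.0,
  0.0,0.5,0.0,0.0,0.5,1.0,0.5,0.0,1.0,0.0,0.5,0.0,1.0,0.0,0.5,0.0,0.5,0.0,0.5,
  0.0,1.0,0.0,0.5,0.0,1.0,0.0,0.5,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.0,
  0.5,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,1.0,0.5,0.0,1.0,0.0,0.0,0.5,0.0,0.5,1.0,
  1.0,0.0,0.5,1.0,0.5,1.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,0.0,0.0,1.0,0.5,1.0,0.5,
  0.0,0.0,0.5,1.0,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,1.0,1.0,0.5,0.0,0.5,1.0,
  0.0,1.0,0.5,0.0,0.5,1.0,1.0,0.5,0.0,0.0,0.0,0.5,1.0,0.5,0.0,1.0,0.0,0.5,1.0,
  0.5,0.0,0.0,0.0,0.5,0.0,1.0,0.5,1.0,0.5,0.5,0.5,1.0,0.5,0.0,0.5,0.5,0.5,0.5,
  0.0,1.0,1.0,0.5,0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,0.0,0.0,0.0,
  0.5,0.5,1.0,0.0,0.0,0.5,1.0,0.5,1.0,0.0,0.0,0.0,0.5,0.5,1.0,0.0,0.0,0.5,1.0,
  0.5,0.5,0.5,0.5,0.5,0.5,0.5,1.0,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,1.0,0.5,
  0.5,0.5,0.5,0.5,0.5,0.0,0.5,1.0,0.5,0.0,1.0,0.5,1.0,1.0,0.0,0.5,1.0,0.5,0.0,
  1.0,0.0,0.5,1.0,0.5,1.0,1.0,0.0,1.0,0.5,0.5,1.0,0.0,0.0,1.0,0.5,0.5,1.0,1.0,
  1.0,1.0,0.5,0.5,1.0,0.0,0.5,1.0,1.0,0.5,1.0,0.0,1.0,1.0,0.5,1.0,0.5,0.0,1.0,
  0.5,1.0,1.0,0.5,0.0,1.0,1.0,0.5,1.0,0.5,0.0,1.0,0.5,1.0,1.0,0.0,0.5,0.5,0.0,
  1.0,1.0,0.0,0.5,1.0,0.5,1.0,0.5,1.0,1.0,0.5,0.0,1.0,1.0,0.5,1.0,0.5,0.0,0.0,
  1.0,0.0,0.5,1.0,0.5,0.0,0.0,1.0,0.5,0.0,0.5,0.0,0.5,1.0,0.0,0.5,0.0,1.0,0.0,
  0.0,0.5,0.0,0.5,1.0,0.5,1.0,1.0,1.0,1.0,0.5,1.0,0.5,1.0,1.0,1.0,0.5,1.0,0.5,
  1.0,0.5,1.0,1.0,0.5,0.0,1.0,0.0,1.0,0.5,0.0,0.5,1.0,0.0,1.0,0.5,0.5,0.0,1.0,
  0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,0.0,0.5,0.0,1.0,0.5,1.0,1.0,1.0,1.0,0.5,1.0,
  0.5,1.0,0.5,1.0,0.0,0.0,1.0,0.5,0.0,0.5,0.0,0.5,0.0,1.0,0.0,0.0,0.5,0.0,0.5,
  1.0,0.5,1.0,1.0,1.0,1.0,0.5,1.0,0.5,1.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.0,0.5,
  0.5,0.0,1.0,1.0,0.5,0.0,0.0,0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,0.0,0.0,
  0.0,0.5,0.0,0.5,1.0,0.5,0.0,1.0,1.0,1.0,0.5,1.0,0.5,1.0,0.5,1.0,1.0,1.0,0.0,
  0.5,1.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,1.0,0.5,0.5,0.5,0.0,0.5,0.0,0.5,0.5,0.5,
  0.5,1.0,1.0,0.0,0.5,0.0,1.0,1.0,0.5,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,0.0,1.0,
  1.0,0.5,0.5,0.0,0.0,1.0,0.5,1.0,0.5,0.0,0.0,1.0,1.0,0.5,0.5,0.0,0.0,1.0,0.5,
  1.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.0,1.0,0.5,0.0,0.0,0.0,0.5,1.0,0.5,0.0,1.0,
  0.5,0.5,0.5,0.5,0.5,0.5,1.0,0.5,1.0,0.5,1.0,1.0,0.5,0.0,1.0,0.0,0.0,0.5,0.0,
  0.5,1.0,1.0,0.5,1.0,0.5,1.0,1.0,1.0,1.0,0.5,0.5,1.0,1.0,0.0,1.0,0.5,1.0,0.5,
  1.0,0.0,1.0,0.5,1.0,0.0,0.5,1.0,0.5,1.0,0.0,1.0,0.5,0.0,0.0,0.5,1.0,0.0,0.5,
  1.0,0.5,1.0,0.5,1.0,1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.5,0.0,0.5,0.0,1.0,
  0.0,0.5,1.0,0.5,1.0,0.0,0.5,0.0,0.5,0.0,0.0,1.0,0.0,0.5,0.0,0.5,0.0,0.0,1.0,
  0.5,0.0,0.0,0.5,0.5,0.0,0.0,1.0,0.5,1.0,0.0,1.0,0.5,0.5,0.0,0.0,1.0,0.5,0.0,
  1.0,0.5,1.0,0.5,0.0,0.0,0.0,1.0,0.5,1.0,0.5,1.0,0.5,1.0,1.0,1.0,0.5,1.0,0.5,
  1.0,1.0,0.0,1.0,0.5,0.0,0.5,0.0,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.5,0.0,1.0,0.5,
  1.0,0.0,0.5,0.0,0.0,0.0,0.5,1.0,0.0,0.5,1.0,0.5,1.0,0.5,1.0,0.0,0.0,0.0,0.5,
  1.0,0.5,1.0,0.5,1.0,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.0,0.5,0.0,0.0,0.0,0.5,0.5,
  1.0,0.0,0.5,0.0,0.0,1.0,0.0,0.5,1.0,0.5,1.0,0.5,1.0,1.0,0.5,0.0,0.0,1.0,0.5,
  1.0,0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,1.0,1.0,0.5,1.0,0.5,0.5,0.5,1.0,0.5,0.0,
  1.0,0.5,1.0,0.5,0.0,0.0,0.5,0.5,0.5,0.5,0.0,0.0,1.0,0.5,1.0,0.0,0.0,0.5,0.5,
  1.0,1.0,0.0,0.0,0.5,1.0,0.5,1.0,0.0,0.0,0.5,0.5,1.0,1.0,0.0,0.5,0.0,0.5,0.5,
  0.5,0.0,0.5,0.0,0.5,1.0,1.0,0.5,1.0,1.0,0.5,1.0,0.0,0.5,0.5,0.5,0.5,0.5,0.5,
  0.5,1.0,0.0,1.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,0.0,0.5,0.5,0.5,1.0,0.5,1.0,0.5,
  1.0,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.5,0.0,1.0,1.0,0.5,1.0,0.5,
  1.0,0.5,1.0,1.0,1.0,0.5,0.0,0.5,1.0,0.0,1.0,0.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,
  0.5,1.0,0.0,1.0,0.0,0.5,0.0,1.0,0.5,0.0,0.0,0.5,0.0,1.0,0.5,0.0,0.5,0.0,0.5,
  1.0,0.0,1.0,0.0,0.5,1.0,0.5,0.0,0.5,0.0,0.0,1.0,1.0,0.5,1.0,0.5,1.0,0.5,1.0,
  1.0,0.0,0.0,0.5,0.5,0.5,0.5,0.0,1.0,0.5,0.0,0.0,0.5,0.5,1.0,1.0,0.5,0.5,0.5,
  0.5,1.0,1.0,0.0,0.0,0.5,1.0,0.5,1.0,0.5,0.0,0.0,1.0,0.5,1.0,0.0,0.0,0.5,1.0,
  0.5,1.0,0.5,0.0,0.0,1.0,1.0,0.5,0.5,0.5,0.5,1.0,1.0,0.5,0.5,0.0,0.0,0.5,0.0,
  0.0,0.5,1.0,0.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,1.0,0.0,0.0,1.0,0.5,0.5,1.0,1.0,
  1.0,1.0,0.5,0.5,0.5,0.5,0.0,1.0,0.5,0.0,0.5,0.0,0.5,1.0,0.0,0.5,1.0,1.0,1.0,
  1.0,0.5,1.0,0.5,1.0,1.0,0.0,0.5,0.5,0.5,0.5,0.0,0.0,0.5,0.5,0.5,0.5,1.0,0.5,
  1.0,0.0,0.0,0.5,0.5,1.0,1.0,0.0,0.0,0.5,1.0,0.5,1.0,0.0,0.0,0.5,0.5,1.0,1.0,
  0.0,0.5,0.0,1.0,1.0,0.5,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,0.0,1.0,1.0,0.5,0.5,
  0.5,0.5,0.5,0.5,0.5,1.0,0.5,0.0,0.0,0.5,0.0,1.0,0.0,0.5,1.0,0.5,0.0,0.5,0.5,
  0.5,0.5,0.5,0.5,1.0,1.0,0.5,1.0,0.5,1.0,1.0,0.5,1.0,0.5,1.0,1.0,1.0,1.0,0.5,
  1.0,0.0,0.5,1.0,0.5,0.0,0.5,0.0,0.0,0.0,0.0,0.5,0.5,0.0,0.0,0.0,0.5,0.0,1.0,
  0.5,1.0,0.5,1.0,1.0,1.0,1.0,0.5,1.0,1.0,0.5,1.0,0.5,1.0,0.5,1.0,1.0,1.0,0.5,
  1.0,1.0,1.0,0.5,0.5,1.0,1.0,0.0,0.5,0.0,0.5,0.0,0.0,0.0,0.0,0.5,1.0,1.0,0.5,
  0.5,1.0,1.0,1.0,0.5,1.0,1.0,0.5,0.0,1.0,1.0,0.5,0.5,0.0,0.0,1.0,1.0,0.5,0.5,
  1.0,1.0,0.5,0.0,0.0,1.0,0.5,1.0,1.0,0.0,0.5,0.5,0.0,0.0,1.0,0.5,1.0,0.5,0.0,
  0.0,0.5,1.0,1.0,0.0,0.0,0.5,1.0,0.5,1.0,1.0,0.0,0.5,1.0,0.5,1.0,0.0,0.0,0.5,
  0.5,1.0,1.0,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.0,0.5,0.5,1.0,1.0,0.0,0.5,0.0,1.0,
  1.0,0.5,1.0,0.5,0.0,1.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,0.5,1.0,0.0,1.0,0.5,
  1.0,0.5,1.0,0.0,0.0,0.5,0.0,1.0,0.5,1.0,0.0,1.0,0.5,0.5,1.0,1.0,1.0,0.5,1.0,
  0.0,1.0,0.5,1.0,0.5,1.0,0.0,0.5,0.0,0.0,1.0,0.5,0.5,1.0,1.0,0.0,0.0,0.5,1.0,
  0.5,1.0,0.0,0.0,0.5,0.5,1.0,1.0,0.0,0.0,0.5,1.0,0.5,1.0,0.5,0.0,0.0,1.0,1.0,
  0.5,0.5,0.0,0.0,1.0,0.5,1.0,0.5,0.0,0.0,1.0,1.0,0.5,0.5,1.0,0.0,0.5,1.0,0.0,
  0.0,1.0,0.5,0.5,1.0,1.0,0.0,1.0,0.5,0.5,1.0,0.0,0.0,0.5,0.0,0.5,0.0,0.0,0.0,
  0.5,0.0,0.5,1.0,0.0,1.0,0.5,0.0,0.5,0.0,0.0,0.5,1.0,0.0,0.5,0.0,0.0,1.0,0.5,
  0.0,1.0,0.0,0.5,1.0,1.0,0.5,1.0,0.0,0.5,1.0,0.5,0.0,1.0,0.0,0.5,1.0,1.0,0.5,
  1.0,0.5,1.0,0.5,1.0,1.0,1.0,0.5,1.0,1.0,1.0,0.5,0.5,1.0,0.0,0.5,1.0,1.0,1.0,
  1.0,0.5,0.5,1.0,0.0,1.0,0.5,0.0,1.0,1.0,0.5,1.0,0.0,0.5,0.5,1.0,1.0,1.0,0.5,
  1.0,0.5,1.0,1.0,1.0,0.0,0.5,0.0,1.0,0.5,0.0,0.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,
  0.5,1.0,1.0,1.0,0.5,1.0,0.5,1.0,0.0,0.5,1.0,0.0,1.0,0.5,1.0,1.0,0.5,0.0,1.0,
  0.5,0.0,0.5,0.0,0.0,1.0,0.5,1.0,0.0,0.0,0.5,1.0,0.5,1.0,0.5,0.0,0.0,1.0,0.5,
  1.0,0.0,0.0,0.5,0.5,1.0,1.0,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.0,0.5,0.5,1.0,1.0,
  0.0,0.5,0.0,0.5,1.0,0.0,1.0,0.0,0.5,0.5,0.0,0.0,1.0,0.5,1.0,0.5,0.0,0.0,0.5,
  1.0,1.0,1.0,0.5,1.0,0.5,0.0,0.0,0.5,1.0,0.0,0.5,1.0,1.0,1.0,0.0,0.5,0.0,0.0,
  0.5,1.0,0.5,1.0,0.0,0.0,0.5,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.0,0.5,1.0,1.0,
  1.0,0.5,1.0,0.0,0.0,0.5,0.0,0.5,0.0,0.5,1.0,0.0,0.5,1.0,1.0,1.0,0.5,1.0,0.0,
  1.0,0.5,1.0,0.5,1.0,0.0,0.5,0.0,0.0,1.0,0.5,1.0,0.5,1.0,1.0,0.5,0.0,0.0,0.5,
  0.0,0.0,0.0,0.5,0.0,1.0,0.5,0.5,0.0,0.0,0.0,1.0,0.5,1.0,0.5,1.0,0.5,0.0,0.0,
  1.0,0.5,1.0,1.0,0.5,0.0,0.5,0.0,0.0,1.0,0.5,1.0,0.0,1.0,0.5,0.5,1.0,1.0,0.5,
  1.0,1.0,1.0,0.5,1.0,0.0,1.0,0.5,0.0,1.0,0.5,1.0,0.5,1.0,0.0,0.5,0.0,1.0,0.5,
  1.0,1.0,0.0,0.5,0.0,0.5,0.0,1.0,0.0,0.5,0.5,0.0,0.0,0.0,0.5,0.0,0.0,1.0,0.5,
  0.5,1.0,1.0,1.0,0.5,1.0,1.0,0.0,0.5,0.0,1.0,0.5,1.0,0.5,1.0,0.0,0.0,0.5,0.0,
  1.0,0.5,1.0,0.0,0.5,0.5,1.0,1.0,0.0,0.5,1.0,1.0,1.0,0.5,0.0,0.5,1.0,0.0,0.0,
  0.5,1.0,1.0,0.5,1.0,1.0,0.5,0.0,0.0,0.5,0.5,0.0,1.0,1.0,0.5,1.0,1.0,1.0,0.5,
  0.5,0.0,1.0,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,1.0,0.5,1.0,1.0,0.0,0.5,0.0,1.0,
  1.0,0.5,0.5,0.0,0.0,1.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,0.5,0.0,0.0,1.0,0.5,
  1.0,0.5,0.0,1.0,1.0,0.5,1.0,0.5,0.0,0.0,0.5,0.0,1.0,0.0,0.0,0.5,0.5,0.0,0.0,
  0.0,0.0,0.5,0.5,0.0,1.0,0.0,0.5,1.0,0.5,1.0,1.0,0.0,0.5,1.0,0.5,0.0,1.0,1.0,
  0.5,1.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,1.0,1.0,1.0,0.5,1.0,1.0,1.0,0.5,1.0,0.0,
  0.5,1.0,1.0,0.5,1.0,0.5,1.0,1.0,1.0,0.5,1.0,0.0,0.5,1.0,0.5,0.0,0.5,0.0,0.0,
  1.0,0.5,0.0,1.0,0.0,0.5,0.5,0.0,1.0,0.5,0.0,0.0,1.0,0.0,0.5,1.0,0.5,1.0,1.0,
  0.0,0.5,0.5,0.0,1.0,1.0,1.0,0.5,0.5,1.0,1.0,1.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,
  0.0,0.5,1.0,1.0,1.0,0.5,0.0,0.0,0.5,1.0,0.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,1.0,
  0.5,1.0,1.0,1.0,1.0,0.5,0.5,1.0,1.0,1.0,0.5,1.0,0.5,1.0,1.0,1.0,1.0,0.5,0.5,
  1.0,0.0,0.5,1.0,1.0,0.5,1.0,0.0,0.0,1.0,0.5,0.0,0.5,0.0,0.0,1.0,0.5,0.5,1.0,
  0.0,0.0,1.0,0.5,0.0,0.5,0.0,0.0,0.5,1.0,0.0,0.0,0.5,0.0,0.5,1.0,0.0,0.5,0.0,
  0.0,0.5,1.0,0.0,0.0,0.5,0.5,0.0,1.0,0.0,0.5,1.0,0.5,0.0,1.0,0.5,1.0,1.0,0.5,
  1.0,1.0,0.0,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,1.0,1.0,0.5,0.5,0.0,1.0,0.5,1.0,
  0.0,0.5,0.0,1.0,1.0,1.0,0.5,0.5,0.0,1.0,0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,0.0,
  1.0,0.5,0.0,1.0,1.0,0.5,0.0,0.5,1.0,0.0,1.0,0.5,0.5,1.0,1.0,0.5,0.0,0.0,0.0,
  0.5,0.0,0.0,0.0,0.5,0.5,0.0,1.0,1.0,0.5,1.0,1.0,0.0,0.5,0.0,0.5,1.0,0.0,1.0,
  0.5,0.5,1.0,1.0,1.0,0.5,0.0,1.0,1.0,0.5,0.5,1.0,0.0,1.0,0.5,1.0,1.0,0.0,0.5,
  0.5,0.0,1.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,1.0,0.5,0.0,1.0,1.0,0.5,0.0,0.0,
  0.0,0.5,0.5,1.0,0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.0,0.5,0.5,1.0,0.0,0.0,0.5,
  1.0,0.5,1.0,1.0,0.0,0.5,1.0,0.5,1.0,0.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,1.0,
  0.5,0.0,1.0,1.0,0.5,0.0,0.5,0.0,0.0,0.5,1.0,1.0,0.0,0.5,1.0,0.5,1.0,0.0,0.0,
  0.5,0.0,0.5,1.0,0.0,0.0,0.5,1.0,1.0,0.5,1.0,1.0,0.0,0.5,0.5,0.0,1.0,0.5,0.0,
  0.0,0.0,0.5,1.0,0.0,0.0,0.5,0.0,0.5,1.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,1.0,0.0,
  0.5,1.0,1.0,0.5,0.0,0.0,0.0,0.5,0.0,0.5,0.5,0.5,0.0,0.5,1.0,0.0,0.5,0.0,0.5,
  0.0,1.0,0.5,0.5,0.5,0.5,0.0,1.0,0.0,0.5,0.0,1.0,0.0,0.5,0.5,1.0,0.0,1.0,0.0,
  0.5,0.0,0.5,0.0,1.0,0.0,0.5,0.5,1.0,0.0,1.0,0.5,1.0,0.5,0.5,0.5,1.0,0.5,1.0,
  0.5,1.0,0.0,0.5,1.0,0.0,0.5,1.0,1.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,1.0,1.0,0.0,
  0.5,1.0,0.5,0.0,1.0,1.0,0.5,1.0,0.5,0.5,0.5,0.0,0.5,1.0,0.0,1.0,0.5,0.5,1.0,
  1.0,0.0,0.0,0.5,0.5,0.0,1.0,0.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,0.0,0.5,0.0,1.0,
  0.0,0.5,0.0,1.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,0.0,0.5,0.5,0.5,1.0,0.5,1.0,1.0,
  0.5,0.0,0.5,1.0,1.0,0.5,0.5,0.5,0.5,1.0,1.0,1.0,0.5,0.0,0.0,1.0,0.5,0.5,0.0,
  0.0,0.0,1.0,0.5,1.0,0.5,0.0,0.0,1.0,0.5,0.5,0.0,0.0,0.0,0.5,1.0,0.5,0.5,0.5,
  0.0,0.5,1.0,0.5,0.0,0.0,0.5,0.0,0.0,0.5,0.0,1.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,
  0.0,1.0,1.0,0.5,1.0,0.5,1.0,1.0,0.0,0.5,1.0,0.5,0.5,0.5,0.5,0.0,1.0,1.0,0.5,
  1.0,1.0,0.0,0.5,0.5,1.0,1.0,0.0,0.5,1.0,0.0,1.0,0.5,0.5,0.0,0.0,0.0,0.5,0.0,
  0.0,0.0,0.5,0.0,0.5,1.0,0.0,1.0,0.5,0.5,1.0,1.0,0.5,0.0,1.0,1.0,0.5,1.0,1.0,
  0.0,0.5,0.5,0.0,1.0,1.0,0.0,0.5,0.5,1.0,1.0,0.5,1.0,1.0,1.0,0.0,0.5,1.0,1.0,
  0.5,1.0,1.0,0.5,0.5,0.0,0.0,1.0,0.0,0.5,0.5,0.0,0.0,1.0,1.0,0.5,0.0,0.5,0.0,
  0.5,1.0,1.0,0.0,0.5,0.0,1.0,1.0,0.5,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.0,0.5,0.5,
  0.0,1.0,0.0,0.0,0.5,0.5,1.0,1.0,1.0,1.0,0.5,0.5,1.0,1.0,1.0,0.5,0.0,0.5,1.0,
  1.0,0.5,0.0,0.0,1.0,0.5,0.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,0.0,0.0,0.0,0.5,0.0,
  1.0,0.5,0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.5,1.0,1.0,0.0,0.0,0.5,0.5,1.0,1.0,0.5,
  0.0,1.0,0.0,0.0,0.5,0.5,1.0,1.0,1.0,0.5,0.0,1.0,1.0,0.5,1.0,1.0,0.5,0.5,1.0,
  0.0,1.0,0.0,0.5,0.0,0.5,0.0,1.0,0.0,0.5,0.5,1.0,0.0,1.0,0.0,0.5,0.0,0.5,0.0,
  0.5,0.0,1.0,0.0,1.0,0.5,0.5,0.0,1.0,0.0,0.5,0.0,0.5,0.0,1.0,0.0,1.0,0.5,0.5,
  1.0,1.0,0.5,0.0,1.0,0.0,0.0,0.5,0.5,1.0,1.0,0.0,1.0,0.5,0.5,1.0,1.0,0.0,0.0,
  0.5,1.0,1.0,0.5,0.5,0.0,0.0,1.0,0.0,0.5,0.5,0.0,0.0,1.0,1.0,0.5,0.5,1.0,0.0,
  1.0,0.5,0.0,1.0,1.0,0.5,0.5,1.0,0.0,0.5,1.0,1.0,0.0,0.5,0.0,0.0,1.0,0.5,0.0,
  0.5,0.0,0.5,1.0,1.0,0.5,0.0,0.0,0.5,0.0,1.0,0.5,0.0,0.0,0.5,1.0,1.0,0.0,1.0,
  0.5,0.5,0.5,0.5,0.0,0.0,0.5,0.5,0.5,0.5,0.5,1.0,0.0,0.0,0.0,0.5,1.0,0.5,0.0,
  0.0,0.0,0.5,0.5,1.0,0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.5,0.0,1.0,1.0,1.0,0.5,0.5,
  0.0,1.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,1.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5,1.0,
  1.0,0.5,0.0,1.0,0.0,1.0,0.5,0.5,1.0,1.0,0.5,0.5,0.5,0.5,0.5,0.5,1.0,1.0,0.5,
  0.5,1.0,0.0,1.0,0.5,0.0,0.5,1.0,0.0,1.0,0.0,0.5,0.5,1.0,0.0,0.5,0.0,1.0,1.0,
  0.0,0.5,0.5,1.0,0.0,0.5,1.0,1.0,0.5,0.0,1.0,1.0,0.0,0.5,1.0,0.5,0.0,0.5,0.0,
  0.0,0.5,1.0,0.0,0.0,0.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,0.5,1.0,0.0,0.5,0.0,1.0,
  0.5,1.0,1.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,
  0.0,0.0,0.5,1.0,0.0,0.5,1.0,1.0,0.5,0.0,1.0,0.0,0.0,0.5,0.0,0.5,0.0,0.5,1.0,
  0.0,0.5,0.0,1.0,0.0,0.5,0.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,1.0,1.0,
  0.5,0.0,1.0,0.0,1.0,0.5,0.5,0.0,1.0,1.0,0.5,0.0,0.0,1.0,0.5,1.0,0.5,0.0,0.0,
  0.5,0.0,0.0,1.0,0.5,0.5,0.0,1.0,1.0,0.0,0.5,1.0,0.5,0.0,0.0,1.0,0.5,0.5,0.5,
  0.5,0.0,0.0,0.5,0.0,1.0,0.5,0.5,0.0,0.0,0.5,0.5,0.5,0.5,0.0,0.0,0.0,1.0,0.5,
  1.0,0.5,0.0,0.5,1.0,1.0,1.0,0.5,0.0,0.0,1.0,0.5,1.0,0.5,0.0,0.5,1.0,1.0,1.0,
  0.0,0.5,0.5,0.5,0.5,1.0,0.0,0.5,0.5,1.0,1.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,0.5,
  0.5,0.5,0.5,0.5,0.5,0.0,1.0,0.0,0.0,0.5,0.5,0.0,0.0,1.0,0.0,0.5,0.5,0.5,0.5,
  0.5,0.0,0.0,0.0,0.5,0.0,0.0,1.0,0.5,0.5,1.0,1.0,0.5,0.0,0.0,0.0,1.0,0.5,0.5,
  0.0,1.0,0.5,0.0,0.0,0.5,1.0,1.0,0.0,1.0,0.5,0.5,1.0,1.0,0.5,0.0,1.0,0.0,1.0,
  0.5,0.5,0.0,1.0,0.0,0.0,0.5,0.0,0.5,1.0,0.0,0.0,0.5,0.5,1.0,1.0,0.0,0.0,0.5,
  1.0,1.0,0.5,0.5,1.0,1.0,0.0,0.0,0.5,1.0,0.0,0.5,1.0,1.0,0.5,0.0,0.5,1.0,0.0,
  0.5,0.0,0.5,0.0,0.0,1.0,1.0,0.5,0.0,0.5,1.0,0.5,0.0,0.0,1.0,0.0,0.5,1.0,1.0,
  0.5,0.5,0.0,0.0,0.5,1.0,1.0,0.0,0.5,1.0,1.0,1.0,0.5,1.0,0.5,0.0,1.0,1.0,0.5,
  0.5,1.0,1.0,1.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,1.0,0.5,0.0,0.0,1.0,0.5,0.0,0.0,
  0.5,1.0,0.0,0.0,0.5,0.5,0.0,0.0,0.0,0.5,1.0,1.0,0.5,0.0,1.0,1.0,0.5,0.5,1.0,
  1.0,0.0,0.5,1.0,1.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,0.0,1.0,0.5,0.0,0.0,0.5,1.0,
  0.5,1.0,1.0,0.0,0.5,1.0,0.0,1.0,0.5,0.0,0.0,0.5,0.5,1.0,0.0,0.0,0.5,0.0,0.5,
  1.0,0.0,0.0,0.0,0.5,1.0,1.0,0.5,1.0,0.0,0.5,1.0,1.0,0.5,0.0,0.0,0.5,1.0,1.0,
  0.5,0.5,0.5,0.5,1.0,0.0,0.5,0.5,0.5,0.5,0.5,1.0,1.0,1.0,0.0,0.5,0.0,0.5,1.0,
  1.0,0.0,0.5,0.5,1.0,1.0,1.0,0.0,0.5,0.0,0.5,1.0,0.5,0.0,0.0,0.0,1.0,0.5,0.5,
  0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.0,1.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5,1.0,
  0.0,0.5,0.0,0.0,1.0,1.0,0.5,0.5,1.0,0.0,0.5,0.5,0.5,0.5,0.5,0.5,0.0,1.0,0.5,
  0.5,1.0,1.0,0.5,1.0,0.0,1.0,0.5,0.0,1.0,1.0,0.5,0.5,0.0,0.0,0.0,0.5,0.0,0.0,
  0.0,0.5,0.5,1.0,1.0,0.0,0.5,1.0,0.0,1.0,0.5,0.5,1.0,1.0,0.0,0.5,1.0,0.0,1.0,
  0.5,1.0,1.0,0.5,0.5,1.0,0.0,1.0,0.5,0.0,0.5,1.0,0.0,0.5,1.0,1.0,0.0,0.5,1.0,
  1.0,0.0,0.5,0.5,1.0,0.0,0.0,0.5,1.0,0.0,0.0,0.5,1.0,0.0,0.5,0.0,0.5,1.0,0.5,
  1.0,0.0,1.0,0.0,0.5,1.0,0.5,0.0,0.0,0.5,0.0,0.5,0.5,0.5,0.0,0.5,1.0,0.5,0.5,
  0.5,0.5,0.0,0.0,0.0,0.5,1.0,1.0,0.0,0.5,0.0,0.5,1.0,0.5,0.0,0.0,0.0,0.5,1.0,
  1.0,0.0,0.5,0.5,1.0,1.0,1.0,0.5,0.0,0.5,1.0,1.0,1.0,0.0,0.5,0.5,1.0,1.0,1.0,
  0.5,0.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,1.0,0.0,0.5,1.0,1.0,0.0,0.5,0.0,0.5,1.0,
  0.0,0.5,0.5,0.5,0.5,0.5,0.5,1.0,0.5,0.0,0.5,0.0,0.0,0.5,1.0,1.0,0.0,0.5,1.0,
  0.0,0.0,0.5,0.5,0.0,0.0,0.5,1.0,1.0,0.0,0.0,0.5,0.5,1.0,0.0,0.5,1.0,1.0,0.5,
  0.0,0.0,0.5,1.0,1.0,0.0,0.5,1.0,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,0.0,0.5,1.0,
  0.0,1.0,0.0,0.5,0.5,0.5,0.5,0.0,0.0,0.5,1.0,0.0,0.5,0.0,0.5,1.0,0.5,0.5,0.5,
  0.0,0.5,1.0,1.0,0.0,0.5,0.5,1.0,1.0,1.0,0.5,0.0,0.5,1.0,1.0,1.0,0.0,0.5,0.5,
  1.0,1.0,1.0,0.5,0.0,0.0,1.0,0.5,0.5,0.5,0.5,0.0,1.0,0.5,1.0,0.5,0.0,1.0,0.5,
  0.0,0.0,0.5,0.0,0.5,0.5,0.5,0.5,0.5,0.5,0.0,0.5,0.0,0.0,0.0,0.5,0.0,0.5,1.0,
  0.0,1.0,0.5,0.5,0.5,0.5,0.0,0.5,1.0,0.0,1.0,0.5,0.5,1.0,1.0,0.5,0.0,0.0,1.0,
  0.0,0.5,1.0,0.5,0.0,0.0,0.0,0.5,0.5,0.0,0.0,0.0,0.5,0.0,0.0,0.5,1.0,0.0,1.0,
  0.5,0.5,1.0,1.0,0.0,1.0,0.5,0.5,1.0,1.0,0.0,0.5,1.0,1.0,0.5,1.0,1.0,1.0,0.5,
  0.0,0.5,1.0,0.0,0.5,1.0,1.0,1.0,0.5,0.0,1.0,0.5,0.0,1.0,0.5,0.0,0.5,0.0,1.0,
  1.0,0.5,0.5,0.0,0.0,1.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,0.5,0.0,0.0,1.0,0.5,
  1.0,0.0,0.0,0.5,1.0,0.5,1.0,0.5,0.0,0.0,1.0,0.5,1.0,0.0,0.0,0.5,0.0,0.5,1.0,
  0.0,1.0,0.5,1.0,0.5,0.0,1.0,1.0,0.5,1.0,0.5,0.0,0.0,1.0,0.5,0.5,0.0,0.0,0.0,
  0.5,1.0,0.5,0.0,0.0,0.0,1.0,0.5,0.5,0.0,0.0,0.0,0.5,1.0,1.0,0.0,0.5,1.0,0.5,
  1.0,1.0,0.0,0.5,0.0,0.5,1.0,1.0,0.5,0.0,0.0,1.0,0.5,0.0,0.5,0.0,0.0,1.0,0.5,
  1.0,0.5,0.0,1.0,1.0,0.5,0.0,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,1.0,0.5,1.0,1.0,
  0.0,0.5,0.0,0.5,1.0,0.5,1.0,0.0,0.0,0.5,0.0,1.0,1.0,0.5,0.0,0.5,0.0,1.0,0.5,
  1.0,1.0,1.0,0.5,0.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,1.0,0.5,1.0,0.0,0.5,0.0,0.0,
  0.0,0.0,0.5,1.0,0.5,1.0,0.5,1.0,0.0,0.0,0.0,0.5,0.0,0.5,1.0,1.0,0.5,1.0,0.0,
  0.0,0.5,1.0,1.0,0.5,0.5,1.0,0.0,1.0,0.5,1.0,1.0,0.5,0.0,1.0,1.0,0.5,0.5,1.0,
  0.0,1.0,0.0,0.5,0.5,0.0,0.0,1.0,0.5,1.0,0.0,0.5,0.0,1.0,0.5,1.0,0.5,0.0,0.0,
  1.0,0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,1.0,0.5,0.5,0.5,0.0,0.5,1.0,0.5,
  0.5,0.5,1.0,1.0,0.5,0.0,0.5,1.0,0.5,1.0,0.0,0.0,0.5,1.0,1.0,1.0,0.5,0.0,0.5,
  1.0,0.5,1.0,0.0,0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.0,0.5,0.5,1.0,0.0,0.0,0.0,0.5,
  1.0,0.5,0.0,0.5,0.5,0.5,0.5,0.5,0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,0.5,1.0,1.0,
  0.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,1.0,0.5,0.0,1.0,1.0,0.5,0.0,1.0,0.5,0.0,0.5,
  1.0,0.5,1.0,0.0,0.0,0.5,1.0,1.0,0.5,0.0,0.5,1.0,0.0,0.0,0.5,1.0,1.0,0.5,1.0,
  1.0,0.5,0.0,0.5,1.0,0.0,0.0,1.0,0.5,0.0,0.5,0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.0,
  0.0,0.5,0.5,0.0,0.0,0.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,1.0,1.0,0.5,0.0,0.0,0.5,
  1.0,0.0,0.5,1.0,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.5,0.0,0.0,0.0,1.0,0.5,
  0.5,0.0,0.0,0.5,1.0,0.0,0.0,1.0,0.5,0.5,0.0,0.0,1.0,0.5,1.0,1.0,0.0,0.5,1.0,
  0.5,1.0,0.5,0.5,0.5,0.0,0.5,1.0,1.0,0.5,1.0,0.0,1.0,0.5,0.5,0.5,0.5,0.0,1.0,
  0.5,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.0,0.5,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.0,
  1.0,0.0,0.5,0.0,0.5,0.0,0.5,0.5,0.5,0.0,0.5,0.0,1.0,0.0,0.5,1.0,0.0,0.5,0.0,
  0.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.0,0.0,0.5,0.0,0.5,1.0,0.0,1.0,0.5,0.0,0.5,
  0.0,0.5,0.5,0.5,1.0,0.5,1.0,0.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,1.0,1.0,0.5,0.0,
  0.0,0.5,0.0,1.0,0.5,0.0,0.5,0.0,0.0,0.0,0.0,0.5,0.0,0.5,1.0,1.0,0.5,0.0,0.0,
  0.0,0.5,1.0,0.5,1.0,1.0,0.5,0.0,0.0,0.5,1.0,1.0,0.5,1.0,1.0,0.0,0.5,0.5,0.0,
  0.0,0.0,0.5,0.0,1.0,0.5,1.0,0.5,0.0,0.0,0.0,0.5,1.0,1.0,0.5,1.0,0.0,0.5,0.0,
  1.0,0.5,1.0,1.0,0.0,0.5,0.0,0.0,0.5,1.0,0.5,1.0,0.0,0.0,0.5,0.0,0.5,1.0,1.0,
  0.5,1.0,1.0,1.0,0.5,0.5,0.0,1.0,1.0,1.0,0.5,0.0,0.0,0.5,0.5,0.0,1.0,1.0,1.0,
  0.5,0.0,1.0,0.5,0.0,0.0,0.5,0.5,0.0,0.0,0.5,0.0,1.0,1.0,0.5,1.0,0.0,1.0,0.5,
  0.5,0.0,0.0,1.0,0.5,1.0,1.0,1.0,0.5,0.0,1.0,0.5,1.0,0.5,1.0,0.5,0.0,0.0,0.0,
  1.0,0.5,0.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,1.0,1.0,0.0,0.5,1.0,1.0,0.5,0.5,0.0,
  0.0,1.0,0.5,0.0,0.5,0.0,0.0,1.0,1.0,0.5,0.0,0.0,0.5,0.0,1.0,0.5,0.0,0.0,0.5,
  1.0,1.0,0.5,1.0,0.5,0.0,0.5,0.5,0.5,0.0,0.5,0.0,0.5,0.5,0.5,1.0,0.0,0.5,0.0,
  0.5,0.0,0.5,0.0,1.0,0.0,0.5,0.0,1.0,0.0,0.5,0.0,0.5,0.0,0.5,0.0,1.0,0.0,1.0,
  0.5,1.0,0.5,1.0,0.0,1.0,0.5,0.5,0.0,1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.5,0.5,0.5,
  0.5,0.5,0.5,1.0,1.0,0.5,0.0,1.0,0.5,1.0,0.5,0.0,1.0,1.0,0.5,0.5,0.5,0.5,0.5,
  0.5,0.5,1.0,0.5,1.0,1.0,0.0,0.5,1.0,1.0,0.5,0.5,1.0,0.0,0.0,0.5,0.0,1.0,1.0,
  0.5,0.0,0.5,0.0,0.0,0.0,0.5,1.0,0.5,1.0,1.0,1.0,0.5,0.0,0.0,0.5,0.5,0.0,1.0,
  1.0,0.5,1.0,0.0,0.0,0.5,0.5,0.0,1.0,1.0,0.5,1.0,1.0,1.0,0.5,0.5,1.0,0.0,0.5,
  0.0,1.0,1.0,1.0,0.5,0.5,0.0,0.0,0.5,0.0,1.0,0.5,1.0,0.0,0.0,0.5,0.0,0.0,0.0,
  0.5,0.5,0.0,0.0,1.0,0.5,1.0,1.0,0.0,0.5,0.5,0.0,1.0,1.0,0.5,0.0,1.0,1.0,0.5,
  0.5,1.0,0.0,1.0,0.0,0.5,0.5,0.0,1.0,1.0,0.5,1.0,1.0,0.5,0.0,1.0,1.0,0.5,0.5,
  1.0,0.0,1.0,0.5,1.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,0.0,0.0,1.0,0.5,0.5,0.0,
  1.0,0.0,1.0,0.5,0.0,0.0,0.5,0.5,0.0,1.0,1.0,0.5,0.0,0.5,1.0,0.0,0.0,1.0,0.5,
  1.0,0.5,0.0,0.5,0.5,0.5,1.0,0.5,1.0,0.5,0.5,0.5,0.5,1.0,0.0,1.0,0.5,1.0,0.0,
  1.0,0.5,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.5,1.0,0.0,1.0,0.5,0.5,0.0,1.0,0.0,0.5,
  0.0,0.5,0.0,1.0,0.0,1.0,0.5,0.5,0.0,1.0,0.0,0.5,0.0,0.5,0.5,0.5,0.5,0.5,0.5,
  0.5,0.0,0.0,0.5,0.0,1.0,1.0,0.5,0.0,0.5,0.0,0.0,0.5,0.5,0.5,0.5,0.5,0.5,0.0,
  0.5,0.0,0.5,1.0,0.0,0.0,0.0,0.5,0.5,0.5,0.5,0.0,1.0,0.5,0.5,0.5,0.5,0.5,0.0,
  1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.5,0.5,0.0,1.0,0.0,1.0,0.5,1.0,0.5,1.0,
  0.5,1.0,0.0,1.0,0.0,0.5,0.5,1.0,0.0,1.0,0.5,1.0,0.5,1.0,0.0,1.0,0.0,0.5,0.5,
  0.5,0.5,0.5,0.5,0.5,0.5,0.0,0.0,0.5,1.0,0.0,0.0,0.0,0.5,0.5,0.0,0.0,0.5,0.5,
  0.5,0.5,0.5,0.5,1.0,0.0,0.5,0.5,0.0,1.0,0.5,0.0,1.0,1.0,0.5,1.0,1.0,0.0,0.5,
  0.0,1.0,0.5,0.0,0.5,0.0,0.5,1.0,0.0,0.0,0.5,0.0,0.0,0.0,0.5,0.5,0.0,1.0,1.0,
  0.5,1.0,0.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,0.0,0.0,0.5,0.0,1.0,0.5,1.0,1.0,0.5,
  0.0,0.5,0.0,0.0,0.5,0.0,1.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,0.5,1.0,0.5,0.0,1.0,
  1.0,0.5,1.0,1.0,0.0,0.5,0.0,0.0,0.5,0.5,0.0,0.0,0.0,0.5,0.0,1.0,0.5,1.0,1.0,
  0.0,0.5,0.5,0.0,1.0,0.5,0.0,1.0,1.0,0.0,0.5,0.0,0.5,1.0,1.0,0.0,0.5,0.0,1.0,
  0.5,0.0,0.5,1.0,1.0,0.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,0.0,0.0,0.5,0.0,0.5,1.0,
  0.5,0.0,1.0,0.0,0.5,0.0,0.5,0.0,0.0,0.0,1.0,0.5,1.0,0.0,0.5,0.0,1.0,0.5,0.5,
  0.0,0.0,0.0,1.0,0.5,1.0,0.0,0.5,1.0,1.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,0.0,0.5,
  1.0,0.5,0.0,0.0,1.0,1.0,0.5,0.0,0.5,1.0,0.5,0.0,1.0,0.5,0.0,0.0,0.0,0.5,1.0,
  1.0,0.5,0.0,1.0,1.0,0.5,0.5,0.0,0.0,1.0,0.5,0.0,0.5,0.5,0.5,0.0,0.5,0.0,1.0,
  0.5,0.0,0.0,0.0,0.5,0.5,0.5,0.5,0.0,0.0,0.5,1.0,0.5,0.0,0.5,0.0,1.0,1.0,1.0,
  0.5,0.5,0.0,1.0,1.0,0.5,0.0,0.5,0.0,1.0,1.0,1.0,0.5,0.0,0.5,1.0,0.5,0.5,0.5,
  0.0,0.5,1.0,1.0,1.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.0,
  1.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,0.0,0.5,1.0,0.5,0.5,0.5,1.0,0.0,0.5,1.0,1.0,
  0.5,0.5,0.0,1.0,1.0,1.0,0.5,0.0,0.5,0.0,0.5,0.0,1.0,0.0,0.5,0.0,0.0,0.5,1.0,
  0.5,0.0,1.0,0.0,0.5,0.0,1.0,1.0,0.5,0.5,1.0,0.0,1.0,1.0,0.5,0.5,0.5,0.5,1.0,
  0.0,0.5,1.0,1.0,0.5,0.5,0.0,1.0,0.5,0.5,0.5,0.5,0.0,1.0,1.0,1.0,0.5,0.0,0.5,
  1.0,0.5,1.0,0.0,0.0,0.5,1.0,1.0,1.0,0.5,0.0,0.5,1.0,0.5,1.0,0.0,0.0,0.0,0.5,
  0.5,0.5,0.5,0.0,0.0,0.5,0.5,1.0,0.0,0.5,1.0,0.0,0.5,0.0,0.0,0.5,0.5,0.5,0.5,
  0.5,0.5,0.5,0.0,0.0,1.0,0.0,0.5,0.5,0.0,1.0,0.0,0.0,0.5,0.5,0.5,0.5,0.0,0.5,
  1.0,0.5,0.5,0.5,0.0,0.5,0.0,0.0,0.5,1.0,0.5,1.0,0.0,0.5,0.5,0.5,0.5,1.0,0.0,
  0.0,0.5,1.0,1.0,1.0,0.5,0.5,0.0,1.0,1.0,1.0,0.5,0.0,0.5,1.0,1.0,1.0,0.5,0.5,
  0.0,1.0,1.0,0.5,0.0,0.5,0.5,0.5,1.0,0.5,0.0,0.5,0.0,1.0,0.5,0.0,1.0,0.5,0.0,
  0.0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.0,0.0,0.0,0.5,0.0,0.5,1.0,0.0,1.0,0.5,0.0,
  0.5,0.5,0.5,0.0,0.0,0.5,0.0,0.5,1.0,0.5,0.0,1.0,0.5,1.0,0.0,1.0,0.5,0.0,1.0,
  1.0,0.5,1.0,0.5,0.0,0.5,1.0,0.0,1.0,0.0,0.5,1.0,0.0,0.5,0.5,1.0,0.0,0.5,0.0,
  1.0,0.5,1.0,0.0,0.0,1.0,0.5,0.5,0.0,1.0,0.0,1.0,0.5,0.0,0.5,1.0,0.5,0.0,1.0,
  0.5,0.0,0.0,1.0,0.0,0.5,1.0,0.5,0.0,0.5,0.0,1.0,0.0,0.0,0.5,0.0,0.5,1.0,0.5,
  1.0,0.0,0.0,1.0,0.5,0.0,0.5,0.0,0.5,1.0,0.0,0.0,1.0,0.5,0.0,0.5,1.0,0.5,0.0,
  1.0,0.5,1.0,0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.5,1.0,0.0,0.5,0.0,1.0,0.0,0.5,1.0,
  0.5,0.0,1.0,0.0,0.0,0.5,0.0,1.0,0.5,0.0,0.5,0.0,0.5,1.0,0.0,0.0,0.5,1.0,0.5,
  0.0,1.0,1.0,0.0,0.5,1.0,0.5,0.0,0.0,0.5,1.0,1.0,0.0,0.5,0.0,0.5,0.0,0.0,0.5,
  1.0,1.0,0.5,0.0,0.0,0.0,0.5,0.0,0.5,1.0,0.5,0.0,1.0,0.5,0.0,0.0,1.0,0.0,0.5,
  1.0,0.5,0.0,0.5,0.0,0.0,0.0,0.5,0.0,0.0,0.5,1.0,0.5,0.0,0.0,0.0,0.5,1.0,0.5,
  0.0,1.0,0.0,0.5,1.0,0.5,0.0,1.0,0.0,0.0,0.5,1.0,0.0,0.5,0.0,1.0,0.5,0.0,0.0,
  0.5,1.0,1.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,0.0,1.0,0.5,0.0,0.5,0.0,0.5,0.0,0.0,
  1.0,0.0,0.5,0.0,1.0,0.5,0.5,0.0,0.0,1.0,1.0,0.5,0.0,1.0,0.5,1.0,0.0,0.5,0.0,
  0.0,0.5,0.5,0.0,0.0,1.0,0.5,0.0,1.0,1.0,0.5,0.0,0.0,0.5,1.0,0.5,0.0,0.0,1.0,
  0.5,0.0,0.0,0.5,1.0,1.0,0.5,0.0,1.0,0.5,0.0,0.5,0.0,1.0,0.5,0.0,0.0,1.0,0.5,
  1.0,0.5,0.0,1.0,1.0,0.5,1.0,1.0,0.5,0.5,1.0,0.0,0.0,0.5,0.0,0.0,0.0,0.5,1.0,
  1.0,0.5,0.0,0.5,0.0,1.0,0.0,0.5,1.0,1.0,0.5,0.0,0.0,0.5,0.5,0.0,0.0,1.0,0.0,
  0.5,1.0,1.0,0.5,0.5,0.0,0.0,1.0,1.0,0.5,0.5,1.0,0.0,0.0,0.5,0.0,0.0,0.0,0.5,
  0.5,0.0,0.0,0.5,1.0,0.0,1.0,0.5,0.0,1.0,1.0,0.5,1.0,1.0,0.5,0.5,1.0,0.0,1.0,
  0.5,0.0,1.0,0.0,0.5,1.0,0.5,0.0,0.5,1.0,0.0,0.0,1.0,0.5,1.0,0.0,0.5,0.5,1.0,
  0.0,0.0,0.0,0.5,1.0,0.0,0.5,0.0,1.0,0.5,0.5,0.0,0.0,1.0,0.0,0.5,1.0,0.5,0.0,
  0.0,0.5,0.0,0.5,1.0,0.0,0.0,1.0,0.5,0.5,1.0,0.0,0.0,1.0,0.5,0.0,0.0,0.5,0.5,
  1.0,0.0,0.0,0.0,0.5,0.5,0.0,0.0,0.5,1.0,0.0,0.0,1.0,0.5,0.0,0.5,0.0,0.0,0.5,
  0.0,0.0,0.0,0.5,1.0,0.0,0.5,0.0,0.5,0.0,1.0,0.0,0.5,1.0,0.5,0.0,1.0,0.5,0.0,
  0.5,0.0,0.0,1.0,0.0,0.5,0.5,0.0,0.0,0.0,0.5,0.0,0.0,0.0,0.5)
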