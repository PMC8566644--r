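#!/usr/bin/env python
"""Independent reference implementation of the 107-feature radiomics vector.

Reads a JSON file with a list of fixtures, each:
    {"dims": [nx, ny, nz], "spacing": [dx, dy, dz],
     "image": [...column-major...], "mask": [...column-major 0/1...],
     "binWidth": w}
and writes a JSON list of {feature_name: value} dicts.

Conventions (IBSI-style, fixed bin width):
  * grey level of v = floor((v - min(masked)) / binWidth) + 1
  * GLCM/GLRLM: 13 unique 3D directions at distance 1, features averaged
  * GLSZM zones / segmentation: 26-connectivity
  * GLDM: 26-neighbourhood, alpha = 0, dependence column = count + 1
  * NGTDM: 26-neighbourhood mean of in-mask neighbours
  * shape: marching-cubes mesh (level 0.5, zero-padded mask); principal
    axes from the population covariance of voxel-centre coordinates
  * first-order Entropy/Uniformity on the discretised histogram;
    population moments; kurtosis not excess-corrected
No shared code with the R implementation under validation.
"""
import json
import sys

import numpy as np
from scipy import ndimage
from skimage.measure import marching_cubes

EPS = 2.2e-16

DIRECTIONS = [(dx, dy, dz)
              for dx in (-1, 0, 1) for dy in (-1, 0, 1) for dz in (-1, 0, 1)
              if (dz > 0) or (dz == 0 and (dy > 0 or (dy == 0 and dx > 0)))]


def first_order(vals, bin_width, spacing):
    n = vals.size
    lev = np.floor((vals - vals.min()) / bin_width).astype(int)
    p = np.bincount(lev).astype(float) / n
    p = p[p > 0]
    mu = vals.mean()
    m2 = ((vals - mu) ** 2).mean()
    m3 = ((vals - mu) ** 3).mean()
    m4 = ((vals - mu) ** 4).mean()
    p10, p25, p75, p90 = np.percentile(vals, [10, 25, 75, 90])
    mid = vals[(vals >= p10) & (vals <= p90)]
    return {
        "firstorder.Energy": float((vals ** 2).sum()),
        "firstorder.TotalEnergy": float(np.prod(spacing) * (vals ** 2).sum()),
        "firstorder.Entropy": float(-(p * np.log2(p)).sum()),
        "firstorder.Minimum": float(vals.min()),
        "firstorder.10Percentile": float(p10),
        "firstorder.90Percentile": float(p90),
        "firstorder.Maximum": float(vals.max()),
        "firstorder.Mean": float(mu),
        "firstorder.Median": float(np.median(vals)),
        "firstorder.InterquartileRange": float(p75 - p25),
        "firstorder.Range": float(vals.max() - vals.min()),
        "firstorder.MeanAbsoluteDeviation": float(np.abs(vals - mu).mean()),
        "firstorder.RobustMeanAbsoluteDeviation":
            float(np.abs(mid - mid.mean()).mean()),
        "firstorder.RootMeanSquared": float(np.sqrt((vals ** 2).mean())),
        "firstorder.Skewness": float(m3 / m2 ** 1.5) if m2 > 0 else 0.0,
        "firstorder.Kurtosis": float(m4 / m2 ** 2) if m2 > 0 else 0.0,
        "firstorder.Variance": float(m2),
        "firstorder.Uniformity": float((p ** 2).sum()),
    }


def shape_features(mask, spacing):
    padded = np.pad(mask.astype(float), 1)
    verts, faces, _, _ = marching_cubes(padded, 0.5)
    verts = (verts - 1.0) * np.asarray(spacing)   # back to unpadded mm coords
    a, b, c = verts[faces[:, 0]], verts[faces[:, 1]], verts[faces[:, 2]]
    cr = np.cross(b - a, c - a)
    area = 0.5 * np.linalg.norm(cr, axis=1).sum()
    vol = abs(np.einsum("ij,ij->i", a, np.cross(b, c)).sum()) / 6.0

    uv = np.unique(verts.round(9), axis=0)
    def max_dist(pts):
        if len(pts) < 2:
            return 0.0
        best = 0.0
        for s in range(0, len(pts), 512):
            blk = pts[s:s + 512]
            d2 = ((blk[:, None, :] - pts[None, :, :]) ** 2).sum(-1)
            best = max(best, float(d2.max()))
        return float(np.sqrt(best))

    def planar(fixed_axis):
        keep = [i for i in range(3) if i != fixed_axis]
        best = 0.0
        for val in np.unique(uv[:, fixed_axis]):
            pts = uv[uv[:, fixed_axis] == val][:, keep]
            best = max(best, max_dist(pts))
        return best

    idx = np.argwhere(mask).astype(float) * np.asarray(spacing)
    ctr = idx - idx.mean(0)
    if len(idx) > 1:
        lam = np.sort(np.linalg.eigvalsh(ctr.T @ ctr / len(ctr)))[::-1]
        lam = np.clip(lam, 0, None)
    else:
        lam = np.zeros(3)
    return {
        "shape.MeshVolume": float(vol),
        "shape.VoxelVolume": float(mask.sum() * np.prod(spacing)),
        "shape.SurfaceArea": float(area),
        "shape.SurfaceVolumeRatio": float(area / vol),
        "shape.Sphericity": float((36 * np.pi * vol ** 2) ** (1 / 3) / area),
        "shape.Maximum3DDiameter": max_dist(uv),
        "shape.Maximum2DDiameterSlice": planar(2),
        "shape.Maximum2DDiameterColumn": planar(0),
        "shape.Maximum2DDiameterRow": planar(1),
        "shape.MajorAxisLength": float(4 * np.sqrt(lam[0])),
        "shape.MinorAxisLength": float(4 * np.sqrt(lam[1])),
        "shape.LeastAxisLength": float(4 * np.sqrt(lam[2])),
        "shape.Elongation": float(np.sqrt(lam[1] / lam[0])) if lam[0] > 0 else 0.0,
        "shape.Flatness": float(np.sqrt(lam[2] / lam[0])) if lam[0] > 0 else 0.0,
    }


def glcm_features(lv):
    gvals = np.unique(lv[~np.isnan(lv)]).astype(int)
    G = len(gvals)
    pos = {g: i for i, g in enumerate(gvals)}
    per_angle = []
    for d in DIRECTIONS:
        sl_a, sl_b = [], []
        for axis, off in enumerate(d):
            n = lv.shape[axis]
            if off >= 0:
                sl_a.append(slice(0, n - off)); sl_b.append(slice(off, n))
            else:
                sl_a.append(slice(-off, n)); sl_b.append(slice(0, n + off))
        A = lv[tuple(sl_a)].ravel()
        B = lv[tuple(sl_b)].ravel()
        ok = ~np.isnan(A) & ~np.isnan(B)
        if not ok.any():
            continue
        ia = np.array([pos[int(v)] for v in A[ok]])
        ib = np.array([pos[int(v)] for v in B[ok]])
        cnt = np.zeros((G, G))
        np.add.at(cnt, (ia, ib), 1)
        cnt = cnt + cnt.T
        per_angle.append(glcm_from_p(cnt / cnt.sum(), gvals.astype(float), G))
    keys = per_angle[0].keys()
    return {k: float(np.mean([f[k] for f in per_angle])) for k in keys}


def glcm_from_p(p, g, Ng):
    i = g[:, None] * np.ones((1, Ng))
    j = i.T
    px = p.sum(1); py = p.sum(0)
    ux = (g * px).sum(); uy = (g * py).sum()
    sx = np.sqrt((px * (g - ux) ** 2).sum())
    sy = np.sqrt((py * (g - uy) ** 2).sum())
    dk = np.abs(i - j)
    kd = np.unique(dk)
    pd = np.array([p[dk == k].sum() for k in kd])
    ks = i + j
    kss = np.unique(ks)
    ps = np.array([p[ks == k].sum() for k in kss])
    da = (kd * pd).sum()
    ent = lambda q: float(-(q[q > 0] * np.log2(q[q > 0] + EPS)).sum())
    hx, hy, hxy = ent(px), ent(py), ent(p)
    pxpy = np.outer(px, py)
    hxy1 = float(-(p[p > 0] * np.log2(pxpy[p > 0] + EPS)).sum())
    hxy2 = ent(pxpy)
    if Ng > 1:
        Q = (p / (px[:, None] + EPS)) @ (p.T / (py[:, None] + EPS))
        ev = np.sort(np.real(np.linalg.eigvals(Q)))[::-1]
        mcc = float(np.sqrt(max(ev[1], 0)))
    else:
        mcc = 1.0
    return {
        "glcm.Autocorrelation": float((p * i * j).sum()),
        "glcm.ClusterProminence": float((p * (i + j - ux - uy) ** 4).sum()),
        "glcm.ClusterShade": float((p * (i + j - ux - uy) ** 3).sum()),
        "glcm.ClusterTendency": float((p * (i + j - ux - uy) ** 2).sum()),
        "glcm.Contrast": float((p * (i - j) ** 2).sum()),
        "glcm.Correlation":
            float(((p * i * j).sum() - ux * uy) / (sx * sy)) if sx * sy > 0 else 1.0,
        "glcm.DifferenceAverage": float(da),
        "glcm.DifferenceEntropy": ent(pd),
        "glcm.DifferenceVariance": float((pd * (kd - da) ** 2).sum()),
        "glcm.Id": float((pd / (1 + kd)).sum()),
        "glcm.Idm": float((pd / (1 + kd ** 2)).sum()),
        "glcm.Idmn": float((pd / (1 + kd ** 2 / Ng ** 2)).sum()),
        "glcm.Idn": float((pd / (1 + kd / Ng)).sum()),
        "glcm.Imc1":
            float((hxy - hxy1) / max(hx, hy)) if max(hx, hy) > 0 else 0.0,
        "glcm.Imc2": float(np.sqrt(max(1 - np.exp(-2 * (hxy2 - hxy)), 0))),
        "glcm.InverseVariance": float((pd[kd > 0] / kd[kd > 0] ** 2).sum()),
        "glcm.JointAverage": float(ux),
        "glcm.JointEnergy": float((p ** 2).sum()),
        "glcm.JointEntropy": hxy,
        "glcm.MCC": mcc,
        "glcm.MaximumProbability": float(p.max()),
        "glcm.SumAverage": float((kss * ps).sum()),
        "glcm.SumEntropy": ent(ps),
        "glcm.SumSquares": float((p * (i - ux) ** 2).sum()),
    }


def si_matrix_features(P, gvals, Np, prefix, names):
    """Shared i/j-emphasis feature formulas for GLRLM/GLSZM-style matrices."""
    Nz = P.sum()
    jj = np.arange(1, P.shape[1] + 1, dtype=float)
    i2 = gvals.astype(float) ** 2
    j2 = jj ** 2
    ri = P.sum(1); rj = P.sum(0)
    p = P / Nz
    mu_i = (p.sum(1) * gvals).sum()
    mu_j = (p.sum(0) * jj).sum()
    vals = {
        "GreyLevelNonUniformity": (ri ** 2).sum() / Nz,
        "GreyLevelNonUniformityNormalized": (ri ** 2).sum() / Nz ** 2,
        "GreyLevelVariance": (p.sum(1) * (gvals - mu_i) ** 2).sum(),
        "High": (ri * i2).sum() / Nz,
        "Long": (rj * j2).sum() / Nz,
        "LongHigh": (P * np.outer(i2, j2)).sum() / Nz,
        "LongLow": (P * np.outer(1 / i2, j2)).sum() / Nz,
        "Low": (ri / i2).sum() / Nz,
        "Entropy": -(p[p > 0] * np.log2(p[p > 0] + EPS)).sum(),
        "SizeNonUniformity": (rj ** 2).sum() / Nz,
        "SizeNonUniformityNormalized": (rj ** 2).sum() / Nz ** 2,
        "Percentage": Nz / Np,
        "SizeVariance": (p.sum(0) * (jj - mu_j) ** 2).sum(),
        "Short": (rj / j2).sum() / Nz,
        "ShortHigh": (P * np.outer(i2, 1 / j2)).sum() / Nz,
        "ShortLow": (P * np.outer(1 / i2, 1 / j2)).sum() / Nz,
    }
    return {prefix + names[k]: float(v) for k, v in vals.items()}


GLRLM_NAMES = {
    "GreyLevelNonUniformity": "GreyLevelNonUniformity",
    "GreyLevelNonUniformityNormalized": "GreyLevelNonUniformityNormalized",
    "GreyLevelVariance": "GreyLevelVariance",
    "High": "HighGreyLevelRunEmphasis",
    "Long": "LongRunEmphasis",
    "LongHigh": "LongRunHighGreyLevelEmphasis",
    "LongLow": "LongRunLowGreyLevelEmphasis",
    "Low": "LowGreyLevelRunEmphasis",
    "Entropy": "RunEntropy",
    "SizeNonUniformity": "RunLengthNonUniformity",
    "SizeNonUniformityNormalized": "RunLengthNonUniformityNormalized",
    "Percentage": "RunPercentage",
    "SizeVariance": "RunVariance",
    "Short": "ShortRunEmphasis",
    "ShortHigh": "ShortRunHighGreyLevelEmphasis",
    "ShortLow": "ShortRunLowGreyLevelEmphasis",
}

GLSZM_NAMES = {
    "GreyLevelNonUniformity": "GreyLevelNonUniformity",
    "GreyLevelNonUniformityNormalized": "GreyLevelNonUniformityNormalized",
    "GreyLevelVariance": "GreyLevelVariance",
    "High": "HighGreyLevelZoneEmphasis",
    "Long": "LargeAreaEmphasis",
    "LongHigh": "LargeAreaHighGreyLevelEmphasis",
    "LongLow": "LargeAreaLowGreyLevelEmphasis",
    "Low": "LowGreyLevelZoneEmphasis",
    "Entropy": "ZoneEntropy",
    "SizeNonUniformity": "SizeZoneNonUniformity",
    "SizeNonUniformityNormalized": "SizeZoneNonUniformityNormalized",
    "Percentage": "ZonePercentage",
    "SizeVariance": "ZoneVariance",
    "Short": "SmallAreaEmphasis",
    "ShortHigh": "SmallAreaHighGreyLevelEmphasis",
    "ShortLow": "SmallAreaLowGreyLevelEmphasis",
}


def glrlm_features(lv):
    gvals = np.unique(lv[~np.isnan(lv)]).astype(int)
    G = len(gvals)
    pos = {g: i for i, g in enumerate(gvals)}
    dims = lv.shape
    Np = int((~np.isnan(lv)).sum())
    per_angle = []
    for d in DIRECTIONS:
        runs = {}
        starts = [tuple(c) for c in np.argwhere(np.ones(dims, bool))
                  if not all(0 <= c[k] - d[k] < dims[k] for k in range(3))]
        for start in starts:
            x, y, z = start
            cur_val, cur_len = None, 0
            while 0 <= x < dims[0] and 0 <= y < dims[1] and 0 <= z < dims[2]:
                v = lv[x, y, z]
                v = None if np.isnan(v) else int(v)
                if v is not None and v == cur_val:
                    cur_len += 1
                else:
                    if cur_val is not None:
                        runs[(cur_val, cur_len)] = runs.get((cur_val, cur_len), 0) + 1
                    cur_val, cur_len = v, (1 if v is not None else 0)
                x, y, z = x + d[0], y + d[1], z + d[2]
            if cur_val is not None:
                runs[(cur_val, cur_len)] = runs.get((cur_val, cur_len), 0) + 1
        max_len = max(l for (_, l) in runs)
        P = np.zeros((G, max_len))
        for (g, l), cnt in runs.items():
            P[pos[g], l - 1] += cnt
        per_angle.append(si_matrix_features(P, gvals.astype(float), Np,
                                            "glrlm.", GLRLM_NAMES))
    keys = per_angle[0].keys()
    return {k: float(np.mean([f[k] for f in per_angle])) for k in keys}


def glszm_features(lv):
    gvals = np.unique(lv[~np.isnan(lv)]).astype(int)
    G = len(gvals)
    Np = int((~np.isnan(lv)).sum())
    structure = np.ones((3, 3, 3), int)
    zones = {}
    for gi, g in enumerate(gvals):
        m = np.nan_to_num(lv, nan=-1) == g
        lab, n = ndimage.label(m, structure=structure)
        for size in np.bincount(lab.ravel())[1:]:
            zones[(gi, int(size))] = zones.get((gi, int(size)), 0) + 1
    max_size = max(s for (_, s) in zones)
    P = np.zeros((G, max_size))
    for (gi, s), cnt in zones.items():
        P[gi, s - 1] += cnt
    return si_matrix_features(P, gvals.astype(float), Np, "glszm.", GLSZM_NAMES)


def neighbour_stacks(lv):
    """For each voxel: list of 26-neighbour values (NaN-padded borders)."""
    p = np.pad(lv, 1, constant_values=np.nan)
    stacks = []
    for dx in (-1, 0, 1):
        for dy in (-1, 0, 1):
            for dz in (-1, 0, 1):
                if dx == dy == dz == 0:
                    continue
                stacks.append(p[1 + dx:p.shape[0] - 1 + dx,
                                1 + dy:p.shape[1] - 1 + dy,
                                1 + dz:p.shape[2] - 1 + dz])
    return np.stack(stacks, axis=-1)


def gldm_features(lv):
    gvals = np.unique(lv[~np.isnan(lv)]).astype(int)
    G = len(gvals)
    pos = {g: i for i, g in enumerate(gvals)}
    nb = neighbour_stacks(lv)
    dep = np.nansum(nb == lv[..., None], axis=-1).astype(int)
    inmask = ~np.isnan(lv)
    jv = dep[inmask] + 1
    iv = np.array([pos[int(v)] for v in lv[inmask]])
    Nd = jv.max()
    P = np.zeros((G, Nd))
    np.add.at(P, (iv, jv - 1), 1)
    f = si_matrix_features(P, gvals.astype(float), int(inmask.sum()),
                           "gldm.", GLSZM_NAMES)
    # GLDM naming differs from the shared template
    return {
        "gldm.DependenceEntropy": f["gldm.ZoneEntropy"],
        "gldm.DependenceNonUniformity": f["gldm.SizeZoneNonUniformity"],
        "gldm.DependenceNonUniformityNormalized":
            f["gldm.SizeZoneNonUniformityNormalized"],
        "gldm.DependenceVariance": f["gldm.ZoneVariance"],
        "gldm.GreyLevelNonUniformity": f["gldm.GreyLevelNonUniformity"],
        "gldm.GreyLevelVariance": f["gldm.GreyLevelVariance"],
        "gldm.HighGreyLevelEmphasis": f["gldm.HighGreyLevelZoneEmphasis"],
        "gldm.LargeDependenceEmphasis": f["gldm.LargeAreaEmphasis"],
        "gldm.LargeDependenceHighGreyLevelEmphasis":
            f["gldm.LargeAreaHighGreyLevelEmphasis"],
        "gldm.LargeDependenceLowGreyLevelEmphasis":
            f["gldm.LargeAreaLowGreyLevelEmphasis"],
        "gldm.LowGreyLevelEmphasis": f["gldm.LowGreyLevelZoneEmphasis"],
        "gldm.SmallDependenceEmphasis": f["gldm.SmallAreaEmphasis"],
        "gldm.SmallDependenceHighGreyLevelEmphasis":
            f["gldm.SmallAreaHighGreyLevelEmphasis"],
        "gldm.SmallDependenceLowGreyLevelEmphasis":
            f["gldm.SmallAreaLowGreyLevelEmphasis"],
    }


def ngtdm_features(lv):
    nb = neighbour_stacks(lv)
    cnt = (~np.isnan(nb)).sum(-1)
    ssum = np.nansum(nb, axis=-1)
    inmask = ~np.isnan(lv)
    use = inmask & (cnt > 0)
    vals = lv[use].astype(int)
    abar = ssum[use] / cnt[use]
    gvals = np.unique(vals)
    Ngp = len(gvals)
    Nvp = len(vals)
    si = np.array([np.abs(g - abar[vals == g]).sum() for g in gvals])
    ni = np.array([(vals == g).sum() for g in gvals])
    pi = ni / Nvp
    gi = gvals.astype(float)
    imat = gi[:, None] - gi[None, :]
    coarse = (pi * si).sum()
    busy_den = np.abs((gi * pi)[:, None] - (gi * pi)[None, :]).sum()
    psum = pi[:, None] + pi[None, :]
    pssum = (pi * si)[:, None] + (pi * si)[None, :]
    return {
        "ngtdm.Busyness":
            float((pi * si).sum() / busy_den) if Ngp > 1 and busy_den > 0 else 0.0,
        "ngtdm.Coarseness": float(1 / coarse) if coarse > 0 else 1e6,
        "ngtdm.Complexity":
            float((np.abs(imat) * pssum / psum).sum() / Nvp),
        "ngtdm.Contrast":
            float((np.outer(pi, pi) * imat ** 2).sum() / (Ngp * (Ngp - 1))
                  * si.sum() / Nvp) if Ngp > 1 else 0.0,
        "ngtdm.Strength":
            float((psum * imat ** 2).sum() / si.sum()) if si.sum() > 0 else 0.0,
    }


def extract(fix):
    dims = fix["dims"]
    spacing = np.asarray(fix["spacing"], float)
    img = np.asarray(fix["image"], float).reshape(dims, order="F")
    mask = np.asarray(fix["mask"]).reshape(dims, order="F") > 0
    w = float(np.asarray(fix["binWidth"]).ravel()[0])
    vals = img[mask]
    lev = np.floor((vals - vals.min()) / w) + 1
    lv = np.full(dims, np.nan)
    lv[mask] = lev
    out = {}
    out.update(first_order(vals, w, spacing))
    out.update(shape_features(mask, spacing))
    out.update(glcm_features(lv))
    out.update(glrlm_features(lv))
    out.update(glszm_features(lv))
    out.update(gldm_features(lv))
    out.update(ngtdm_features(lv))
    assert len(out) == 107, len(out)
    return out


def main():
    with open(sys.argv[1]) as fh:
        fixtures = json.load(fh)
    results = [extract(f) for f in fixtures]
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
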