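#!/usr/bin/env python
"""One-time generator for the packaged minimal-basis molecular fixtures.

Computes STO-3G integrals for H2, He and LiH with a McMurchie-Davidson
scheme (s and p shells), runs a restricted Hartree-Fock SCF, transforms the
integrals to the converged MO basis, and writes standard FCIDUMP files plus
a plain-text metadata table with independently computed RHF and FCI
energies (determinant-enumeration FCI over spin orbitals).

Validation gates (the script aborts if any fails):
  * H2/STO-3G at R = 1.4 bohr reproduces the canonical published MO-basis
    integrals (Szabo & Ostlund): h11 = -1.2528, h22 = -0.4756,
    (11|11) = 0.6746, (11|22) = 0.6636, (12|12) = 0.1813, and
    E_RHF = -1.1167 hartree.
  * He/STO-3G reproduces E_RHF = -2.80778 hartree.
  * LiH/STO-3G at R = 3.015 bohr reproduces E_RHF = -7.862 hartree.

Run from the repository root:  python data-raw/make_fixtures.py
"""
import itertools
import math
import os

import numpy as np
from scipy.special import hyp1f1

OUTDIR = os.path.join(os.path.dirname(__file__), "..", "inst", "extdata")

# ---------------------------------------------------------------- basis ----
# Standard STO-3G exponents/contractions (already scaled).
STO3G = {
    "H": [("s", [3.425250914, 0.6239137298, 0.1688554040],
           [0.1543289673, 0.5353281423, 0.4446345422])],
    "He": [("s", [6.362421394, 1.158922999, 0.3136497915],
            [0.1543289673, 0.5353281423, 0.4446345422])],
    "Li": [("s", [16.11957475, 2.936200663, 0.7946504870],
            [0.1543289673, 0.5353281423, 0.4446345422]),
           ("s", [0.6362897469, 0.1478600533, 0.0480886784],
            [-0.09996722919, 0.3995128261, 0.7001154689]),
           ("p", [0.6362897469, 0.1478600533, 0.0480886784],
            [0.1559162750, 0.6076837186, 0.3919573931])]}

CHARGE = {"H": 1, "He": 2, "Li": 3}


class CGF:
    """Contracted cartesian Gaussian x^i y^j z^k exp(-a r^2)."""

    def __init__(self, center, lmn, exps, coefs):
        self.center = np.asarray(center, float)
        self.lmn = lmn
        self.exps = list(exps)
        # include primitive norms
        self.coefs = [c * prim_norm(a, lmn) for c, a in zip(coefs, exps)]

    def normalize(self, s_self):
        self.coefs = [c / math.sqrt(s_self) for c in self.coefs]


def prim_norm(a, lmn):
    l = sum(lmn)
    if l == 0:
        return (2 * a / math.pi) ** 0.75
    if l == 1:
        return (2 * a / math.pi) ** 0.75 * 2 * math.sqrt(a)
    raise ValueError("only s and p shells supported")


def build_basis(atoms):
    basis = []
    for sym, center in atoms:
        for kind, exps, coefs in STO3G[sym]:
            if kind == "s":
                basis.append(CGF(center, (0, 0, 0), exps, coefs))
            else:
                for lmn in [(1, 0, 0), (0, 1, 0), (0, 0, 1)]:
                    basis.append(CGF(center, lmn, exps, coefs))
    return basis


# ------------------------------------------- McMurchie-Davidson kernels ----
def e_coef(i, j, t, qx, a, b):
    """Hermite expansion coefficient E_t^{ij} for a 1D Gaussian product."""
    p = a + b
    mu = a * b / p
    if t < 0 or t > i + j:
        return 0.0
    if i == j == t == 0:
        return math.exp(-mu * qx * qx)
    if j == 0:  # decrement i
        return (e_coef(i - 1, j, t - 1, qx, a, b) / (2 * p)
                - (mu * qx / a) * e_coef(i - 1, j, t, qx, a, b)
                + (t + 1) * e_coef(i - 1, j, t + 1, qx, a, b))
    return (e_coef(i, j - 1, t - 1, qx, a, b) / (2 * p)
            + (mu * qx / b) * e_coef(i, j - 1, t, qx, a, b)
            + (t + 1) * e_coef(i, j - 1, t + 1, qx, a, b))


def boys(n, x):
    return hyp1f1(n + 0.5, n + 1.5, -x) / (2.0 * n + 1.0)


def r_herm(t, u, v, n, p, pc):
    """Hermite Coulomb auxiliary R^n_{tuv}."""
    if t < 0 or u < 0 or v < 0:
        return 0.0
    if t == u == v == 0:
        return (-2.0 * p) ** n * boys(n, p * float(np.dot(pc, pc)))
    if t > 0:
        return ((t - 1) * r_herm(t - 2, u, v, n + 1, p, pc)
                + pc[0] * r_herm(t - 1, u, v, n + 1, p, pc))
    if u > 0:
        return ((u - 1) * r_herm(t, u - 2, v, n + 1, p, pc)
                + pc[1] * r_herm(t, u - 1, v, n + 1, p, pc))
    return ((v - 1) * r_herm(t, u, v - 2, n + 1, p, pc)
            + pc[2] * r_herm(t, u, v - 1, n + 1, p, pc))


def overlap_prim(a, la, ra, b, lb, rb):
    p = a + b
    q = ra - rb
    s = (math.pi / p) ** 1.5
    for x in range(3):
        s *= e_coef(la[x], lb[x], 0, q[x], a, b)
    return s


def kinetic_prim(a, la, ra, b, lb, rb):
    def s1(lb_mod):
        if min(lb_mod) < 0:
            return 0.0
        return overlap_prim(a, la, ra, b, tuple(lb_mod), rb)

    t = 0.0
    for x in range(3):
        lb_ = list(lb)
        term = b * (2 * lb[x] + 1) * s1(lb_)
        lb_[x] += 2
        term -= 2 * b * b * s1(lb_)
        lb_[x] -= 4
        term -= 0.5 * lb[x] * (lb[x] - 1) * s1(lb_)
        t += term
    return t


def nuclear_prim(a, la, ra, b, lb, rb, rc):
    p = a + b
    rp = (a * ra + b * rb) / p
    pc = rp - rc
    val = 0.0
    for t in range(la[0] + lb[0] + 1):
        et = e_coef(la[0], lb[0], t, (ra - rb)[0], a, b)
        for u in range(la[1] + lb[1] + 1):
            eu = e_coef(la[1], lb[1], u, (ra - rb)[1], a, b)
            for v in range(la[2] + lb[2] + 1):
                ev = e_coef(la[2], lb[2], v, (ra - rb)[2], a, b)
                val += et * eu * ev * r_herm(t, u, v, 0, p, pc)
    return 2 * math.pi / p * val


def eri_prim(a, la, ra, b, lb, rb, c, lc, rc, d, ld, rd):
    p = a + b
    q = c + d
    alpha = p * q / (p + q)
    rp = (a * ra + b * rb) / p
    rq = (c * rc + d * rd) / q
    pq = rp - rq
    val = 0.0
    for t in range(la[0] + lb[0] + 1):
        e1t = e_coef(la[0], lb[0], t, (ra - rb)[0], a, b)
        for u in range(la[1] + lb[1] + 1):
            e1u = e_coef(la[1], lb[1], u, (ra - rb)[1], a, b)
            for v in range(la[2] + lb[2] + 1):
                e1v = e_coef(la[2], lb[2], v, (ra - rb)[2], a, b)
                for tt in range(lc[0] + ld[0] + 1):
                    e2t = e_coef(lc[0], ld[0], tt, (rc - rd)[0], c, d)
                    for uu in range(lc[1] + ld[1] + 1):
                        e2u = e_coef(lc[1], ld[1], uu, (rc - rd)[1], c, d)
                        for vv in range(lc[2] + ld[2] + 1):
                            e2v = e_coef(lc[2], ld[2], vv, (rc - rd)[2], c, d)
                            val += (e1t * e1u * e1v * e2t * e2u * e2v
                                    * (-1.0) ** (tt + uu + vv)
                                    * r_herm(t + tt, u + uu, v + vv, 0,
                                             alpha, pq))
    return val * 2 * math.pi ** 2.5 / (p * q * math.sqrt(p + q))


def contract2(kernel, f1, f2, *extra):
    out = 0.0
    for a, ca in zip(f1.exps, f1.coefs):
        for b, cb in zip(f2.exps, f2.coefs):
            out += ca * cb * kernel(a, f1.lmn, f1.center,
                                    b, f2.lmn, f2.center, *extra)
    return out


def integrals(atoms):
    basis = build_basis(atoms)
    n = len(basis)
    s = np.array([[contract2(overlap_prim, basis[i], basis[j])
                   for j in range(n)] for i in range(n)])
    for i, f in enumerate(basis):
        f.normalize(s[i, i])
    s = np.array([[contract2(overlap_prim, basis[i], basis[j])
                   for j in range(n)] for i in range(n)])
    t = np.array([[contract2(kinetic_prim, basis[i], basis[j])
                   for j in range(n)] for i in range(n)])
    v = np.zeros((n, n))
    for sym, center in atoms:
        rc = np.asarray(center, float)
        v -= CHARGE[sym] * np.array(
            [[contract2(nuclear_prim, basis[i], basis[j], rc)
              for j in range(n)] for i in range(n)])
    eri = np.zeros((n, n, n, n))
    for i, j, k, l in itertools.product(range(n), repeat=4):
        if eri[i, j, k, l] != 0.0:
            continue
        val = 0.0
        for (a, ca), (b, cb), (c, cc), (d, cd) in itertools.product(
                zip(basis[i].exps, basis[i].coefs),
                zip(basis[j].exps, basis[j].coefs),
                zip(basis[k].exps, basis[k].coefs),
                zip(basis[l].exps, basis[l].coefs)):
            val += ca * cb * cc * cd * eri_prim(
                a, basis[i].lmn, basis[i].center, b, basis[j].lmn,
                basis[j].center, c, basis[k].lmn, basis[k].center,
                d, basis[l].lmn, basis[l].center)
        for p, q, r, w in {(i, j, k, l), (j, i, k, l), (i, j, l, k),
                           (j, i, l, k), (k, l, i, j), (l, k, i, j),
                           (k, l, j, i), (l, k, j, i)}:
            eri[p, q, r, w] = val
    e_nuc = 0.0
    for (s1_, r1), (s2_, r2) in itertools.combinations(atoms, 2):
        e_nuc += CHARGE[s1_] * CHARGE[s2_] / np.linalg.norm(
            np.asarray(r1, float) - np.asarray(r2, float))
    return s, t + v, eri, e_nuc


# --------------------------------------------------------------- RHF/FCI ---
def rhf(s, h, eri, e_nuc, nelec):
    n = h.shape[0]
    nocc = nelec // 2
    sval, svec = np.linalg.eigh(s)
    x = svec @ np.diag(sval ** -0.5) @ svec.T
    c = None
    dm = np.zeros((n, n))
    e_old = 0.0
    for it in range(200):
        g = np.einsum("ls,mnsl->mn", dm, eri) \
            - 0.5 * np.einsum("ls,mlsn->mn", dm, eri)
        f = h + g
        eps, cp = np.linalg.eigh(x.T @ f @ x)
        c = x @ cp
        dm_new = 2.0 * c[:, :nocc] @ c[:, :nocc].T
        e = 0.5 * np.sum(dm_new * (h + f))
        if abs(e - e_old) < 1e-12 and np.max(np.abs(dm_new - dm)) < 1e-10:
            dm = dm_new
            break
        dm = dm_new
        e_old = e
    g = np.einsum("ls,mnsl->mn", dm, eri) \
        - 0.5 * np.einsum("ls,mlsn->mn", dm, eri)
    f = h + g
    e = 0.5 * np.sum(dm * (h + f)) + e_nuc
    return e, c


def fci(h_mo, eri_mo, e_nuc, nelec):
    """Determinant FCI over spin orbitals (independent oracle, tiny n)."""
    n = h_mo.shape[0]
    na = nb = nelec // 2
    amasks = [sum(1 << (2 * p) for p in occ)
              for occ in itertools.combinations(range(n), na)]
    bmasks = [sum(1 << (2 * p + 1) for p in occ)
              for occ in itertools.combinations(range(n), nb)]
    dets = [a | b for a in amasks for b in bmasks]
    idx = {d: i for i, d in enumerate(dets)}
    dim = len(dets)
    hmat = np.zeros((dim, dim))

    def ann(mask, so):
        if not mask & (1 << so):
            return None
        sgn = 1 if bin(mask & ((1 << so) - 1)).count("1") % 2 == 0 else -1
        return mask ^ (1 << so), sgn

    def cre(mask, so):
        if mask & (1 << so):
            return None
        sgn = 1 if bin(mask & ((1 << so) - 1)).count("1") % 2 == 0 else -1
        return mask | (1 << so), sgn

    for ket, d in enumerate(dets):
        occ = [so for so in range(2 * n) if d & (1 << so)]
        for q in occ:
            m1, s1_ = ann(d, q)
            for p in range(q % 2, 2 * n, 2):
                r = cre(m1, p)
                if r is None:
                    continue
                hmat[idx[r[0]], ket] += h_mo[p // 2, q // 2] * s1_ * r[1]
        for k in occ:
            m1, s1_ = ann(d, k)
            for l in occ:
                if l == k:
                    continue
                a2 = ann(m1, l)
                if a2 is None:
                    continue
                m2, s2_ = a2
                for j in range(l % 2, 2 * n, 2):
                    a3 = cre(m2, j)
                    if a3 is None:
                        continue
                    m3, s3_ = a3
                    for i in range(k % 2, 2 * n, 2):
                        a4 = cre(m3, i)
                        if a4 is None:
                            continue
                        val = eri_mo[i // 2, k // 2, j // 2, l // 2]
                        if val == 0.0:
                            continue
                        hmat[idx[a4[0]], ket] += (0.5 * val * s1_ * s2_
                                                  * s3_ * a4[1])
    return np.linalg.eigvalsh((hmat + hmat.T) / 2)[0] + e_nuc


def mo_transform(h, eri, c):
    h_mo = c.T @ h @ c
    eri_mo = np.einsum("pqrs,pi,qj,rk,sl->ijkl", eri, c, c, c, c,
                       optimize=True)
    return h_mo, eri_mo


def write_fcidump(path, h_mo, eri_mo, e_nuc, nelec):
    n = h_mo.shape[0]
    with open(path, "w") as fh:
        fh.write(f" &FCI NORB={n},NELEC={nelec},MS2=0,\n")
        fh.write("  ORBSYM=" + "1," * n + "\n  ISYM=1,\n &END\n")

        def rec(v, i, j, k, l):
            fh.write(f"{v:23.16E} {i:4d} {j:4d} {k:4d} {l:4d}\n")

        for i in range(1, n + 1):
            for j in range(1, i + 1):
                for k in range(1, i + 1):
                    lmax = j if k == i else k
                    for l in range(1, lmax + 1):
                        v = eri_mo[i - 1, j - 1, k - 1, l - 1]
                        if abs(v) > 1e-12:
                            rec(v, i, j, k, l)
        for i in range(1, n + 1):
            for j in range(1, i + 1):
                if abs(h_mo[i - 1, j - 1]) > 1e-12:
                    rec(h_mo[i - 1, j - 1], i, j, 0, 0)
        rec(e_nuc, 0, 0, 0, 0)


def main():
    os.makedirs(OUTDIR, exist_ok=True)
    systems = {
        "h2": ([("H", (0, 0, 0)), ("H", (0, 0, 1.4))], 2, "R = 1.4 bohr"),
        "he": ([("He", (0, 0, 0))], 2, "atom"),
        "lih": ([("Li", (0, 0, 0)), ("H", (0, 0, 3.015))], 4,
                "R = 3.015 bohr"),
    }
    meta = ["system basis geometry n_orbitals e_rhf_hartree e_fci_hartree"]
    results = {}
    for name, (atoms, nelec, geom) in systems.items():
        s, h, eri, e_nuc = integrals(atoms)
        e_rhf, c = rhf(s, h, eri, e_nuc, nelec)
        h_mo, eri_mo = mo_transform(h, eri, c)
        e_fci = fci(h_mo, eri_mo, e_nuc, nelec)
        results[name] = (h_mo, eri_mo, e_rhf, e_fci)
        print(f"{name}: RHF {e_rhf:.7f}  FCI {e_fci:.7f}  ({len(h)} orbitals)")
        write_fcidump(os.path.join(OUTDIR, f"{name}_sto3g.fcidump"),
                      h_mo, eri_mo, e_nuc, nelec)
        meta.append(f"{name} STO-3G \"{geom}\" {h_mo.shape[0]} "
                    f"{e_rhf:.10f} {e_fci:.10f}")
    with open(os.path.join(OUTDIR, "fixtures_meta.txt"), "w") as fh:
        fh.write("\n".join(meta) + "\n")

    # validation gates (published reference values)
    h_mo, eri_mo, e_rhf, e_fci = results["h2"]
    assert abs(h_mo[0, 0] - (-1.2528)) < 2e-4, h_mo[0, 0]
    assert abs(h_mo[1, 1] - (-0.4756)) < 2e-4, h_mo[1, 1]
    assert abs(eri_mo[0, 0, 0, 0] - 0.6746) < 2e-4
    assert abs(eri_mo[0, 0, 1, 1] - 0.6636) < 2e-4
    assert abs(eri_mo[0, 1, 0, 1] - 0.1813) < 2e-4
    assert abs(e_rhf - (-1.1167)) < 2e-4
    assert abs(results["he"][2] - (-2.80778)) < 1e-4
    assert abs(results["lih"][2] - (-7.862)) < 2e-3
    print("all validation gates passed")


if __name__ == "__main__":
    main()
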