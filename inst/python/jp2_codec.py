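"""JPEG2000 encode/decode helper built on Pillow's OpenJPEG bindings.

Invoked as a subprocess by the R package; prints one JSON document on stdout.
All lossy encodes use the reversible 5/3 wavelet with rate-controlled
codestream truncation, so a single rate axis spans the full quality range up
to exact losslessness (rate 1). PSNR targeting bisects log2(compression
ratio) in [-10, 0]; byte-budget targeting bisects the same axis on the
compressed size.
"""

import argparse
import json
import math
import os
import sys

import numpy as np
from PIL import Image

PSNR_CAP = 100.0


def read_rgb(path):
    img = np.asarray(Image.open(path).convert("RGB"))
    return img


def psnr(ref, deg):
    mse = np.mean((ref.astype(np.float64) - deg.astype(np.float64)) ** 2)
    if mse == 0:
        return PSNR_CAP
    return 10.0 * math.log10(255.0 ** 2 / mse)


def encode_at(img, out_path, rate):
    """Encode with reversible wavelet at the given compression-rate factor.

    rate <= 1 encodes without truncation (exactly lossless)."""
    im = Image.fromarray(img)
    if rate <= 1.0:
        im.save(out_path, format="JPEG2000", irreversible=False)
    else:
        im.save(out_path, format="JPEG2000", irreversible=False,
                quality_mode="rates", quality_layers=[float(rate)])
    dec = read_rgb(out_path)
    return len(open(out_path, "rb").read()), dec


def save_png(img, path):
    Image.fromarray(img).save(path, format="PNG")


def cmd_lossless(args):
    img = read_rgb(args.input)
    nbytes, dec = encode_at(img, args.output, 1.0)
    exact = bool(np.array_equal(dec, img))
    if args.decode_to:
        save_png(dec, args.decode_to)
    print(json.dumps({"bytes": nbytes, "exact": exact,
                      "achieved_psnr": psnr(img, dec)}))


def cmd_encode(args):
    img = read_rgb(args.input)
    nbytes, dec = encode_at(img, args.output, args.rate)
    if args.decode_to:
        save_png(dec, args.decode_to)
    print(json.dumps({"bytes": nbytes, "rate": args.rate,
                      "achieved_psnr": psnr(img, dec)}))


def cmd_decode(args):
    dec = read_rgb(args.input)
    save_png(dec, args.output)
    print(json.dumps({"ok": True}))


def bisect_psnr(img, target, tol, max_iter, out_jp2, out_png):
    """Bisection on x = log2(compression ratio) in [-10, 0]; PSNR is
    nondecreasing in x. Returns the best encode found, flagged converged
    when |achieved - target| <= tol."""
    lo, hi = -10.0, 0.0
    best = None
    iters = 0
    while iters < max_iter:
        x = (lo + hi) / 2.0
        rate = 2.0 ** (-x)
        tmp = out_jp2 + ".try"
        nbytes, dec = encode_at(img, tmp, rate)
        p = psnr(img, dec)
        iters += 1
        if best is None or abs(p - target) < abs(best["achieved_psnr"] - target):
            os.replace(tmp, out_jp2)
            save_png(dec, out_png)
            best = {"achieved_psnr": p, "bytes": nbytes, "rate": rate,
                    "iterations": iters}
        else:
            os.remove(tmp)
        if abs(p - target) <= tol:
            break
        if p < target:
            lo = x
        else:
            hi = x
    best["iterations"] = iters
    best["converged"] = abs(best["achieved_psnr"] - target) <= tol
    best["target"] = target
    return best


def cmd_target(args):
    img = read_rgb(args.input)
    targets = [float(t) for t in args.targets.split(",")]
    out = []
    for t in targets:
        jp2 = "%s_t%g.jp2" % (args.out_prefix, t)
        png = "%s_t%g.png" % (args.out_prefix, t)
        if t >= PSNR_CAP:
            nbytes, dec = encode_at(img, jp2, 1.0)
            save_png(dec, png)
            out.append({"target": t, "achieved_psnr": psnr(img, dec),
                        "bytes": nbytes, "rate": 1.0, "iterations": 1,
                        "converged": True, "jp2": jp2, "png": png})
        else:
            res = bisect_psnr(img, t, args.tol, args.max_iter, jp2, png)
            res.update({"jp2": jp2, "png": png})
            out.append(res)
    print(json.dumps(out))


def cmd_ratio(args):
    """Largest encode whose size is <= max_ratio * raw bytes."""
    img = read_rgb(args.input)
    budget = args.max_ratio * img.size  # H*W*3 bytes raw
    jp2 = args.out_prefix + ".jp2"
    png = args.out_prefix + ".png"
    nbytes, dec = encode_at(img, jp2, 1.0)
    iters = 1
    if nbytes > budget:
        lo, hi = -10.0, 0.0
        best = None
        while iters < args.max_iter and (hi - lo) > 0.01:
            x = (lo + hi) / 2.0
            tmp = jp2 + ".try"
            nb, dc = encode_at(img, tmp, 2.0 ** (-x))
            iters += 1
            if nb <= budget:
                os.replace(tmp, jp2)
                nbytes, dec = nb, dc
                best = x
                lo = x
                if nb >= 0.98 * budget:
                    break
            else:
                os.remove(tmp)
                hi = x
        if best is None:
            print(json.dumps({"error": "byte budget unreachable",
                              "bytes": nbytes, "iterations": iters}))
            return
    save_png(dec, png)
    print(json.dumps({"bytes": nbytes, "achieved_psnr": psnr(img, dec),
                      "iterations": iters, "jp2": jp2, "png": png,
                      "ratio": nbytes / img.size}))


def main():
    ap = argparse.ArgumentParser()
    sub = ap.add_subparsers(dest="mode", required=True)

    p = sub.add_parser("lossless")
    p.add_argument("input"); p.add_argument("output")
    p.add_argument("--decode-to", default=None)
    p.set_defaults(func=cmd_lossless)

    p = sub.add_parser("encode")
    p.add_argument("input"); p.add_argument("output")
    p.add_argument("--rate", type=float, required=True)
    p.add_argument("--decode-to", default=None)
    p.set_defaults(func=cmd_encode)

    p = sub.add_parser("decode")
    p.add_argument("input"); p.add_argument("output")
    p.set_defaults(func=cmd_decode)

    p = sub.add_parser("target")
    p.add_argument("input"); p.add_argument("out_prefix")
    p.add_argument("--targets", required=True)
    p.add_argument("--tol", type=float, default=0.5)
    p.add_argument("--max-iter", type=int, default=30)
    p.set_defaults(func=cmd_target)

    p = sub.add_parser("ratio")
    p.add_argument("input"); p.add_argument("out_prefix")
    p.add_argument("--max-ratio", type=float, required=True)
    p.add_argument("--max-iter", type=int, default=30)
    p.set_defaults(func=cmd_ratio)

    args = ap.parse_args()
    args.func(args)


if __name__ == "__main__":
    main()
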