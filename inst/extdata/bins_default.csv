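start,end,step
74.99,75.11,0.01
101.94,102.06,0.01
106.94,107.06,0.01
111.94,112.06,0.01
116.94,117.06,0.01
121.94,122.06,0.01
126.94,127.06,0.01
131.94,132.06,0.01
136.94,137.06,0.01
141.94,142.06,0.01
146.94,147.06,0.01
151.94,152.06,0.01
156.94,157.06,0.01
161.94,162.06,0.01
166.94,167.06,0.01
171.94,172.06,0.01
176.94,177.06,0.01
181.94,182.06,0.01
186.94,187.06,0.01
191.94,192.06,0.01
196.94,197.06,0.01
201.94,202.06,0.01
206.94,207.06,0.01
211.94,212.06,0.01
216.94,217.06,0.01
221.94,222.06,0.01
226.94,227.06,0.01
231.94,232.06,0.01
236.94,237.06,0.01
241.94,242.06,0.01
246.94,247.06,0.01
251.94,252.06,0.01
256.94,257.06,0.01
261.94,262.06,0.01
266.94,267.06,0.01
271.94,272.06,0.01
276.94,277.06,0.01
281.94,282.06,0.01
286.94,287.06,0.01
291.94,292.06,0.01
296.94,297.06,0.01
305.00,306.00,0.50
310.00,315.00,5.00
320.00,321.00,0.50
335.00,336.00,0.50
350.00,351.00,0.50
365.00,366.00,0.50
370.00,375.00,5.00
380.00,381.00,0.50
395.00,396.00,0.50
410.00,411.00,0.50
425.00,426.00,0.50
430.00,435.00,5.00
440.00,441.00,0.50
455.00,456.00,0.50
470.00,471.00,0.50
485.00,486.00,0.50
490.00,495.00,5.00
500.00,501.00,0.50
515.00,516.00,0.50
530.00,531.00,0.50
545.00,546.00,0.50
550.00,555.00,5.00
560.00,561.00,0.50
575.00,576.00,0.50
590.00,591.00,0.50
605.00,606.00,0.50
610.00,615.00,5.00
620.00,621.00,0.50
635.00,636.00,0.50
650.00,651.00,0.50
665.00,666.00,0.50
670.00,675.00,5.00
680.00,681.00,0.50
695.00,696.00,0.50
710.00,711.00,0.50
725.00,726.00,0.50
730.00,735.00,5.00
740.00,741.00,0.50
755.00,756.00,0.50
770.00,771.00,0.50
785.00,786.00,0.50
809.95,810.05,0.01
829.95,830.05,0.01
849.95,850.05,0.01
869.95,870.05,0.01
889.95,890.05,0.01
909.95,910.05,0.01
929.95,930.05,0.01
949.95,950.05,0.01
969.95,970.05,0.01
989.95,990.05,0.01
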